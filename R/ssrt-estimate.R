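#' Block-wise integration estimate of the stop-signal reaction time
#'
#' Estimates SSRT with the block-wise integration method: within each block
#' the go RTs are sorted ascending, the rank is `n = p(respond|stop) x (number
#' of go RTs)`, and the block SSRT is the n-th go RT minus the block's mean
#' stop-signal delay. The session SSRT is the arithmetic mean of the block
#' values.
#'
#' A non-integer rank is resolved by `rank_rule`: `"ceiling"` (default) takes
#' the ceiling, clamped to `[1, n_go]`; `"interpolate"` linearly interpolates
#' the sorted go RTs between the bracketing ranks. Go omissions (go trials
#' with no response) are excluded from the go-RT distribution by default;
#' `omission_policy = "replace_max"` instead substitutes the block's maximum
#' go RT for each omission, which compensates the rank for trials that would
#' have produced slow responses.
#'
#' @param session An `"sst_session"` tibble (or any data frame with columns
#'   `block`, `type`, `response`, `rt_ms`, `ssd_ms`).
#' @param rank_rule `"ceiling"` or `"interpolate"`.
#' @param omission_policy `"exclude"` or `"replace_max"`.
#'
#' @return An object of class `"ssrt_fit"`: a list with `blocks` (tibble of
#'   per-block `p_respond_stop`, `mean_ssd_ms`, `n_go_rt`, `nth_go_rt_ms`,
#'   `ssrt_ms`) and `ssrt_ms` (session mean). `tidy()` returns the block
#'   table, `glance()` a one-row session summary.
#' @examples
#' sess <- simulate_sst(sst_params(), seed = 2)
#' fit <- estimate_ssrt(sess)
#' glance(fit)
#' @export
estimate_ssrt <- function(session,
                          rank_rule = c("ceiling", "interpolate"),
                          omission_policy = c("exclude", "replace_max")) {
  rank_rule <- match.arg(rank_rule)
  omission_policy <- match.arg(omission_policy)
  stopifnot_param(all(c("block", "type", "response", "rt_ms", "ssd_ms")
                      %in% names(session)),
                  "session must have block/type/response/rt_ms/ssd_ms columns")

  blocks <- lapply(split(as.data.frame(session), session$block), function(bl) {
    b <- bl$block[1]
    go <- bl[bl$type == "go", , drop = FALSE]
    stop_tr <- bl[bl$type == "stop", , drop = FALSE]
    if (nrow(stop_tr) == 0) {
      abort(sprintf("block %s has no stop trials", b),
            class = "stopnet_estimation_error")
    }
    go_rts <- go$rt_ms[go$response]
    go_rts <- go_rts[is.finite(go_rts)]
    if (length(go_rts) == 0) {
      abort(sprintf("block %s has no usable go RTs", b),
            class = "stopnet_estimation_error")
    }
    n_omit <- sum(!go$response)
    if (omission_policy == "replace_max" && n_omit > 0) {
      go_rts <- c(go_rts, rep(max(go_rts), n_omit))
    }
    go_rts <- sort(go_rts)
    p_resp <- mean(stop_tr$response)
    mean_ssd <- mean(stop_tr$ssd_ms)
    nth <- nth_go_rt(go_rts, p_resp, rank_rule)
    tibble(block = b, p_respond_stop = p_resp, mean_ssd_ms = mean_ssd,
           n_go_rt = length(go_rts), nth_go_rt_ms = nth,
           ssrt_ms = nth - mean_ssd)
  })
  blocks <- bind_rows(blocks)
  structure(list(blocks = blocks, ssrt_ms = mean(blocks$ssrt_ms),
                 rank_rule = rank_rule, omission_policy = omission_policy),
            class = "ssrt_fit")
}

# n-th go RT for the integration method; go_rts already sorted ascending.
nth_go_rt <- function(go_rts, p_respond, rank_rule) {
  m <- length(go_rts)
  n <- p_respond * m
  if (rank_rule == "ceiling") {
    r <- min(max(ceiling(n), 1L), m)
    go_rts[r]
  } else {
    if (n <= 1) return(go_rts[1])
    if (n >= m) return(go_rts[m])
    lo <- floor(n)
    w <- n - lo
    go_rts[lo] * (1 - w) + go_rts[lo + 1] * w
  }
}

#' @export
print.ssrt_fit <- function(x, ...) {
  cat(sprintf("<ssrt_fit> session SSRT %.1f ms over %d blocks (%s rank, %s omissions)\n",
              x$ssrt_ms, nrow(x$blocks), x$rank_rule, x$omission_policy))
  print(x$blocks)
  invisible(x)
}

#' @rdname estimate_ssrt
#' @param x,... An `"ssrt_fit"` object; further arguments are ignored.
#' @method tidy ssrt_fit
#' @export
tidy.ssrt_fit <- function(x, ...) x$blocks

#' @rdname estimate_ssrt
#' @method glance ssrt_fit
#' @export
glance.ssrt_fit <- function(x, ...) {
  tibble(ssrt_ms = x$ssrt_ms, n_blocks = nrow(x$blocks),
         mean_p_respond_stop = mean(x$blocks$p_respond_stop),
         mean_ssd_ms = mean(x$blocks$mean_ssd_ms))
}

#' Session-level behavioral summary
#'
#' Aggregates a stop-signal session into the standard task summary: go
#' accuracy, choice-error and omission percentages, the mean of the per-block
#' n-th go RTs, stop-inhibition percentage, mean RT on failed stop trials,
#' mean SSD and the integration SSRT.
#'
#' @param session An `"sst_session"` tibble.
#' @param ssrt An `"ssrt_fit"` for the same session; computed if `NULL`.
#'
#' @return A one-row tibble with columns `go_accuracy_pct`,
#'   `mean_nth_go_rt_ms`, `choice_error_pct`, `omission_pct`,
#'   `stop_inhibit_pct`, `false_inhibit_rt_ms` (`NA` when no stop trial
#'   failed), `mean_ssd_ms`, `ssrt_ms`.
#' @export
summarize_behavior <- function(session, ssrt = NULL) {
  if (is.null(ssrt)) ssrt <- estimate_ssrt(session)
  stopifnot_param(inherits(ssrt, "ssrt_fit"), "ssrt must be an ssrt_fit")
  go <- session[session$type == "go", ]
  st <- session[session$type == "stop", ]
  stop_fail_rt <- st$rt_ms[st$response]
  tibble(
    go_accuracy_pct = 100 * mean(go$response & go$correct),
    mean_nth_go_rt_ms = mean(ssrt$blocks$nth_go_rt_ms),
    choice_error_pct = 100 * mean(go$response & !go$correct),
    omission_pct = 100 * mean(!go$response),
    stop_inhibit_pct = 100 * mean(!st$response),
    false_inhibit_rt_ms = if (length(stop_fail_rt)) mean(stop_fail_rt) else NA_real_,
    mean_ssd_ms = mean(ssrt$blocks$mean_ssd_ms),
    ssrt_ms = ssrt$ssrt_ms
  )
}

#' Tukey whisker outlier mask
#'
#' Flags values below `Q1 - k * IQR` or above `Q3 + k * IQR`, the boxplot
#' whisker rule used for behavioral outlier screening. Quartiles use linear
#' interpolation of the empirical CDF (`stats::quantile` type 7) by default.
#'
#' @param values Numeric vector of at least 4 finite values.
#' @param k Whisker multiplier (default 1.5).
#' @param type Quantile convention passed to [stats::quantile()].
#'
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @examples
#' tukey_outliers(c(1:9, 100))
#' @export
tukey_outliers <- function(values, k = 1.5, type = 7) {
  stopifnot_param(is.numeric(values) && sum(is.finite(values)) >= 4,
                  "need at least 4 finite values")
  q <- quantile(values[is.finite(values)], c(0.25, 0.75),
                type = type, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}
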