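#' Stop-signal task parameters
#'
#' Bundle of race-model and protocol parameters for [simulate_sst()]. The
#' defaults reproduce the standard interleaved dual-staircase protocol: five
#' blocks of 100 go and 40 stop trials, staircases starting at 150 and 350 ms,
#' moving in 50 ms steps within \[0, 800\] ms so that the probability of
#' responding on a stop trial is driven toward 50%.
#'
#' Go-trial finishing times are ex-Gaussian (`go_mu` + normal sd `go_sigma`
#' plus an exponential tail with mean `go_tau`); the stop process finishes
#' `ssrt_true` ms after the stop signal (optionally jittered by a normal with
#' sd `ssrt_sd`). A go trial fails to produce any response with probability
#' `p_go_omission`, and a produced response is the wrong choice with
#' probability `p_choice_error`.
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian go-RT parameters, ms.
#' @param ssrt_true True stop latency (SSRT), ms.
#' @param ssrt_sd Trial-to-trial sd of the stop latency, ms (0 = constant).
#' @param p_go_omission Probability that the go process never finishes.
#' @param p_choice_error Probability a produced response is the wrong choice.
#' @param n_blocks Number of blocks.
#' @param n_go,n_stop Go and stop trials per block.
#' @param ssd_start Numeric vector of staircase starting SSDs, ms.
#' @param ssd_step Staircase step, ms.
#' @param ssd_bounds Length-2 vector of SSD bounds, ms.
#'
#' @return A list of class `"sst_params"`.
#' @seealso [simulate_sst()]
#' @export
sst_params <- function(go_mu = 500, go_sigma = 60, go_tau = 100,
                       ssrt_true = 200, ssrt_sd = 0,
                       p_go_omission = 0.075, p_choice_error = 0.015,
                       n_blocks = 5, n_go = 100, n_stop = 40,
                       ssd_start = c(150, 350), ssd_step = 50,
                       ssd_bounds = c(0, 800)) {
  p <- list(
    go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
    ssrt_true = ssrt_true, ssrt_sd = ssrt_sd,
    p_go_omission = p_go_omission, p_choice_error = p_choice_error,
    n_blocks = as.integer(n_blocks), n_go = as.integer(n_go),
    n_stop = as.integer(n_stop),
    ssd_start = as.numeric(ssd_start), ssd_step = as.numeric(ssd_step),
    ssd_bounds = as.numeric(ssd_bounds)
  )
  validate_sst_params(p)
  structure(p, class = "sst_params")
}

validate_sst_params <- function(p) {
  stopifnot_param(p$go_sigma >= 0, "go_sigma must be >= 0")
  stopifnot_param(p$go_tau >= 0, "go_tau must be >= 0")
  stopifnot_param(p$ssrt_true >= 0, "ssrt_true must be >= 0")
  stopifnot_param(p$ssrt_sd >= 0, "ssrt_sd must be >= 0")
  for (nm in c("p_go_omission", "p_choice_error")) {
    stopifnot_param(p[[nm]] >= 0 && p[[nm]] <= 1,
                    paste(nm, "must lie in [0, 1]"))
  }
  stopifnot_param(p$n_blocks >= 1 && p$n_go >= 1 && p$n_stop >= 1,
                  "trial counts must be positive integers")
  stopifnot_param(p$ssd_step > 0, "ssd_step must be > 0")
  stopifnot_param(length(p$ssd_bounds) == 2 && p$ssd_bounds[1] < p$ssd_bounds[2],
                  "ssd_bounds must be an ordered pair")
  stopifnot_param(length(p$ssd_start) >= 1 &&
                    all(p$ssd_start >= p$ssd_bounds[1]) &&
                    all(p$ssd_start <= p$ssd_bounds[2]),
                  "ssd_start values must lie inside ssd_bounds")
  invisible(p)
}

stopifnot_param <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "stopnet_param_error")
}

#' Simulate a stop-signal session
#'
#' Runs an independent-race simulation of the stop-signal task under the
#' interleaved dual-staircase protocol. On every stop trial a response is
#' emitted iff the sampled go process finishes before `SSD + stop latency`;
#' after a successful stop the staircase's next SSD rises by one step (making
#' stopping harder), after a failed stop it falls by one step, clamped to the
#' configured bounds. The staircases take stop trials in strict alternation,
#' and staircase state carries across blocks. Stop trials are positioned
#' uniformly at random among the go trials of each block.
#'
#' @param params An [sst_params()] object.
#' @param seed Integer seed; all session randomness derives from it.
#'
#' @return A tibble of class `"sst_session"` with one row per trial and
#'   columns `block`, `trial`, `type` (`"go"`/`"stop"`), `stimulus`
#'   (`"left"`/`"right"`), `response` (logical), `correct` (logical),
#'   `rt_ms` (`NA` when no response), `ssd_ms` (`NA` on go trials) and
#'   `staircase` (`NA` on go trials). The parameters are attached as the
#'   `"params"` attribute.
#' @examples
#' sess <- simulate_sst(sst_params(), seed = 1)
#' dplyr::count(sess, block, type)
#' @export
simulate_sst <- function(params = sst_params(), seed = NULL) {
  if (!inherits(params, "sst_params")) params <- do.call(sst_params, params)
  with_seed(seed, {
    n_trials_block <- params$n_go + params$n_stop
    n_stairs <- length(params$ssd_start)
    ssd_state <- params$ssd_start
    stair_cursor <- 0L  # counts stop trials across the whole session

    blocks <- vector("list", params$n_blocks)
    for (b in seq_len(params$n_blocks)) {
      is_stop <- logical(n_trials_block)
      is_stop[sample.int(n_trials_block, params$n_stop)] <- TRUE

      type <- ifelse(is_stop, "stop", "go")
      stimulus <- sample(c("left", "right"), n_trials_block, replace = TRUE)
      go_finish <- params$go_mu + rnorm(n_trials_block, 0, params$go_sigma) +
        rexp(n_trials_block, rate = 1 / params$go_tau)
      go_finish <- pmax(go_finish, 1)
      omitted <- runif(n_trials_block) < params$p_go_omission
      go_finish[omitted] <- Inf
      wrong <- runif(n_trials_block) < params$p_choice_error

      response <- logical(n_trials_block)
      correct <- logical(n_trials_block)
      rt <- rep(NA_real_, n_trials_block)
      ssd <- rep(NA_real_, n_trials_block)
      stair_id <- rep(NA_integer_, n_trials_block)

      for (t in seq_len(n_trials_block)) {
        if (!is_stop[t]) {
          response[t] <- is.finite(go_finish[t])
          if (response[t]) rt[t] <- go_finish[t]
          correct[t] <- response[t] && !wrong[t]
        } else {
          s <- (stair_cursor %% n_stairs) + 1L
          stair_cursor <- stair_cursor + 1L
          stair_id[t] <- s
          ssd[t] <- ssd_state[s]
          stop_finish <- ssd[t] + params$ssrt_true +
            if (params$ssrt_sd > 0) rnorm(1, 0, params$ssrt_sd) else 0
          responded <- is.finite(go_finish[t]) && go_finish[t] < stop_finish
          response[t] <- responded
          if (responded) rt[t] <- go_finish[t]
          correct[t] <- !responded
          delta <- if (responded) -params$ssd_step else params$ssd_step
          ssd_state[s] <- min(max(ssd_state[s] + delta, params$ssd_bounds[1]),
                              params$ssd_bounds[2])
        }
      }

      blocks[[b]] <- tibble(
        block = b, trial = seq_len(n_trials_block), type = type,
        stimulus = stimulus, response = response, correct = correct,
        rt_ms = rt, ssd_ms = ssd, staircase = stair_id
      )
    }
    out <- bind_rows(blocks)
    attr(out, "params") <- params
    class(out) <- c("sst_session", class(out))
    out
  })
}

#' @export
print.sst_session <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<sst_session> %d blocks x (%d go + %d stop) trials, true SSRT %.0f ms\n",
    p$n_blocks, p$n_go, p$n_stop, p$ssrt_true))
  NextMethod()
}

#' Plot the staircase trajectory of a session
#'
#' Shows the stop-signal delay of each staircase across successive stop
#' trials, with the bounds as dashed lines.
#'
#' @param object An `"sst_session"` tibble from [simulate_sst()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sst_session
#' @export
autoplot.sst_session <- function(object, ...) {
  p <- attr(object, "params")
  d <- dplyr::filter(object, .data$type == "stop")
  d <- dplyr::mutate(dplyr::group_by(d, .data$staircase),
                     stop_index = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(.data$stop_index, .data$ssd_ms,
                                  colour = factor(.data$staircase))) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = p$ssd_bounds, linetype = "dashed") +
    ggplot2::labs(x = "stop trial (within staircase)", y = "SSD (ms)",
                  colour = "staircase") +
    ggplot2::theme_minimal()
}
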