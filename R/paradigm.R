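#' Block-design task paradigm
#'
#' Describes a block-design stimulation paradigm: `n_epochs` epochs, each a
#' task block of `task_s` seconds followed (or preceded, see `task_first`)
#' by a rest block of `rest_s` seconds, sampled every `tr_s` seconds
#' (the repetition time, TR).
#'
#' @param n_epochs Number of stimulation epochs (positive integer).
#' @param task_s Task-block duration in seconds (positive).
#' @param rest_s Rest-block duration in seconds (non-negative).
#' @param tr_s Repetition time in seconds (positive). The total duration
#'   `n_epochs * (task_s + rest_s)` must be an integer multiple of `tr_s`.
#' @param task_first If `TRUE` (default) each epoch starts with the task
#'   block at its onset; otherwise rest comes first.
#'
#' @return An object of class `task_paradigm`.
#' @examples
#' p <- task_paradigm(n_epochs = 8, task_s = 20, rest_s = 30, tr_s = 2.5)
#' n_frames(p) # 160
#' @export
task_paradigm <- function(n_epochs = 8, task_s = 20, rest_s = 30, tr_s = 2.5,
                          task_first = TRUE) {
  stopifnot(length(n_epochs) == 1, length(task_s) == 1, length(rest_s) == 1,
            length(tr_s) == 1)
  if (!is.finite(n_epochs) || n_epochs < 1 || n_epochs != round(n_epochs))
    stop("`n_epochs` must be a positive integer")
  if (!is.finite(task_s) || task_s < 0) stop("`task_s` must be >= 0")
  if (!is.finite(rest_s) || rest_s < 0) stop("`rest_s` must be >= 0")
  if (!is.finite(tr_s) || tr_s <= 0) stop("`tr_s` must be > 0")
  total <- n_epochs * (task_s + rest_s)
  if (total <= 0) stop("paradigm has zero duration")
  nf <- total / tr_s
  if (abs(nf - round(nf)) > 1e-8)
    stop("total paradigm duration (", total,
         " s) is not an integer multiple of tr_s (", tr_s, " s)")
  structure(list(n_epochs = as.integer(n_epochs), task_s = task_s,
                 rest_s = rest_s, tr_s = tr_s, task_first = isTRUE(task_first)),
            class = "task_paradigm")
}

#' Number of frames (TRs) in a paradigm
#' @param paradigm A [task_paradigm()].
#' @return Integer number of time points.
#' @export
n_frames <- function(paradigm) {
  stopifnot(inherits(paradigm, "task_paradigm"))
  as.integer(round(paradigm$n_epochs * (paradigm$task_s + paradigm$rest_s) /
                     paradigm$tr_s))
}

#' Task boxcar sampled at the TR grid
#'
#' Value 1 during task blocks, 0 during rest; frame k is sampled at its
#' onset time `(k - 1) * tr_s`.
#'
#' @inheritParams n_frames
#' @return Numeric vector of length [n_frames()].
#' @export
boxcar_regressor <- function(paradigm) {
  stopifnot(inherits(paradigm, "task_paradigm"))
  nf <- n_frames(paradigm)
  t0 <- (seq_len(nf) - 1) * paradigm$tr_s
  epoch_s <- paradigm$task_s + paradigm$rest_s
  phase <- t0 %% epoch_s
  if (paradigm$task_first) as.numeric(phase < paradigm$task_s)
  else as.numeric(phase >= paradigm$rest_s)
}

#' Discrete Gaussian hemodynamic response kernel
#'
#' A Gaussian kernel peaking `peak_s` seconds after stimulus onset with
#' standard deviation `sd_s`, sampled at the TR and normalized so that its
#' discrete integral (`sum * tr_s`) is exactly 1. Support is truncated at
#' `peak_s + 4 * sd_s`.
#'
#' @param tr_s Sampling interval in seconds.
#' @param peak_s Time to peak in seconds (default 5).
#' @param sd_s Kernel standard deviation in seconds (default 2.5).
#' @return Numeric vector of kernel weights.
#' @export
hrf_kernel <- function(tr_s, peak_s = 5, sd_s = 2.5) {
  if (!is.finite(tr_s) || tr_s <= 0) stop("`tr_s` must be > 0")
  if (!is.finite(peak_s) || peak_s <= 0) stop("`peak_s` must be > 0")
  if (!is.finite(sd_s) || sd_s <= 0) stop("`sd_s` must be > 0")
  t <- seq(0, peak_s + 4 * sd_s, by = tr_s)
  g <- stats::dnorm(t, mean = peak_s, sd = sd_s)
  g / (sum(g) * tr_s)
}

#' Expected BOLD regressor for a paradigm
#'
#' The task boxcar convolved with the Gaussian hemodynamic kernel and
#' truncated to the paradigm length. A rest-only paradigm (`task_s = 0`)
#' yields the all-zero series.
#'
#' @inheritParams n_frames
#' @param peak_s,sd_s Gaussian kernel parameters, see [hrf_kernel()].
#' @return Numeric vector of length [n_frames()].
#' @export
hrf_regressor <- function(paradigm, peak_s = 5, sd_s = 2.5) {
  stopifnot(inherits(paradigm, "task_paradigm"))
  box <- boxcar_regressor(paradigm)
  if (all(box == 0)) return(box)
  k <- hrf_kernel(paradigm$tr_s, peak_s, sd_s) * paradigm$tr_s # unit-sum weights
  full <- stats::convolve(box, rev(k), type = "open")
  out <- full[seq_along(box)]
  # convolve() can leave tiny negative ripple at machine precision
  out[abs(out) < 1e-12] <- 0
  out
}
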