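# Equal-variance Gaussian signal detection metrics.

# Internal constructor shared by exact and count-based estimates.
sdt_from_rates <- function(hit_rate, fa_rate, n_signal, n_noise,
                           corrected = FALSE) {
  if (hit_rate == fa_rate) {
    # chance performance; exact rates may sit on the boundary (e.g. the
    # p_d = 0.5 collapse, where the classifier never responds DMS)
    d <- 0
    cc <- -stats::qnorm(hit_rate)
  } else {
    d <- stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
    cc <- -(stats::qnorm(hit_rate) + stats::qnorm(fa_rate)) / 2
  }
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 d_prime = d, criterion_c = cc,
                 n_signal = n_signal, n_noise = n_noise,
                 corrected = corrected),
            class = "sdt_estimate")
}

#' Sensitivity and criterion from response counts
#'
#' Equal-variance Gaussian signal detection estimates from the four outcome
#' counts of a yes/no task: \eqn{d' = z(H) - z(F)} and criterion
#' \eqn{c = -(z(H) + z(F))/2} (positive c = conservative, biased toward
#' responding "random"). Extreme observed rates of 0 or 1 are replaced by
#' \eqn{1/(2N)} and \eqn{1 - 1/(2N)} before the z-transform, where N is the
#' number of trials in that margin; the \code{corrected} flag records when
#' this happened.
#'
#' @param hits,misses trials with a DMS (signal) stimulus answered
#'   DMS / RANDOM.
#' @param fas,crs trials with a random (noise) stimulus answered
#'   DMS / RANDOM.
#' @return an object of class \code{"sdt_estimate"}: hit and false-alarm
#'   rates, \code{d_prime}, \code{criterion_c}, margin counts, and the
#'   correction flag.
#' @examples
#' sdt_from_counts(hits = 40, misses = 10, fas = 15, crs = 35)
#' @export
sdt_from_counts <- function(hits, misses, fas, crs) {
  counts <- c(hits, misses, fas, crs)
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be four non-negative integers", call. = FALSE)
  n_signal <- hits + misses
  n_noise <- fas + crs
  if (n_signal < 1L || n_noise < 1L)
    stop("each stimulus class needs at least one trial", call. = FALSE)
  h <- hits / n_signal
  f <- fas / n_noise
  corrected <- FALSE
  if (h == 0) { h <- 1 / (2 * n_signal); corrected <- TRUE }
  if (h == 1) { h <- 1 - 1 / (2 * n_signal); corrected <- TRUE }
  if (f == 0) { f <- 1 / (2 * n_noise); corrected <- TRUE }
  if (f == 1) { f <- 1 - 1 / (2 * n_noise); corrected <- TRUE }
  sdt_from_rates(h, f, n_signal, n_noise, corrected)
}

#' @export
print.sdt_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("SDT estimate: H = %.*f, F = %.*f, d' = %.*f, c = %.*f%s\n",
              digits, x$hit_rate, digits, x$fa_rate,
              digits, x$d_prime, digits, x$criterion_c,
              if (isTRUE(x$corrected)) " (extreme rates corrected)" else ""))
  invisible(x)
}

#' Score responses against session labels
#'
#' Cross-tabulates per-trial responses with the generating labels of a
#' session and returns the SDT estimate (DMS = signal).
#'
#' @param responses factor/character vector of \code{"RANDOM"}/\code{"DMS"}
#'   responses, or a data frame with a \code{response} column.
#' @param session a \code{\link{build_session}} data frame (or any vector of
#'   true labels).
#' @return an \code{\link{sdt_estimate}}.
#' @export
score_session <- function(responses, session) {
  if (is.data.frame(responses)) responses <- responses$response
  labels <- if (is.data.frame(session)) session$true_label else session
  if (length(responses) != length(labels))
    stop("responses and session have different lengths", call. = FALSE)
  r <- as.character(responses) == "DMS"
  s <- as.character(labels) == "DMS"
  sdt_from_counts(sum(r & s), sum(!r & s), sum(r & !s), sum(!r & !s))
}

#' Efficiency relative to the full Bayesian observer
#'
#' The ratio of an observer's d' in a condition to the exact d' of the full
#' BDT model in the same condition (computed by complete enumeration).
#'
#' @param observer_dprime the observer's d' estimate (a number or an
#'   \code{\link{sdt_estimate}}).
#' @inheritParams ideal_observer
#' @return a list of class \code{"efficiency_record"} with
#'   \code{observer_dprime}, \code{model_dprime} and \code{efficiency}.
#' @examples
#' efficiency(1.2, p_d = 0.1)
#' @export
efficiency <- function(observer_dprime, p_r = 0.9, p_d = 0.1, n = 20L) {
  if (inherits(observer_dprime, "sdt_estimate"))
    observer_dprime <- observer_dprime$d_prime
  full <- exact_performance(ideal_observer(p_r, p_d, n))$d_prime
  if (!is.finite(full) || full <= 0)
    stop("efficiency undefined: full-model d' is not positive", call. = FALSE)
  structure(list(observer_dprime = observer_dprime, model_dprime = full,
                 efficiency = observer_dprime / full,
                 p_r = p_r, p_d = p_d, n = n),
            class = "efficiency_record")
}

#' @export
print.efficiency_record <- function(x, ...) {
  cat(sprintf("efficiency = %.4f (observer d' = %.4f, full model d' = %.4f)\n",
              x$efficiency, x$observer_dprime, x$model_dprime))
  invisible(x)
}
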