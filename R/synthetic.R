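# Synthetic observers: noisy weighted-feature responders with lapses.
# They stand in for human participants so every stage of the fitting
# pipeline (GLM weights, standardization, dominant feature, AICc model
# comparison, SDT scoring) can be validated by parameter recovery.

#' Specify a synthetic observer
#'
#' A synthetic observer responds DMS on each trial with probability
#' \deqn{p = \mathrm{lapse}/2 + (1 - \mathrm{lapse}) \,
#'   \psi(\beta_0 + \textstyle\sum_k \beta_k f_k(S) + \epsilon),}
#' \eqn{\psi} the logistic function and \eqn{\epsilon} zero-mean Gaussian
#' decision noise added to the linear predictor. This is exactly the
#' response model the feature GLM assumes, plus lapse and noise, so
#' parameter recovery is well-posed; lapse = 1 is pure guessing.
#'
#' @param beta0 intercept of the linear predictor.
#' @param beta named numeric vector of generative feature weights, names
#'   among \code{f1..f4}; omitted features have weight 0. The f2 weight
#'   applies to the sign-flipped feature.
#' @param lapse probability in [0, 1] of an attention lapse (fair guess).
#' @param noise_sd SD of the Gaussian decision noise (>= 0).
#' @param id optional observer label.
#' @return an object of class \code{"observer_spec"}.
#' @examples
#' observer_spec(beta0 = -14, beta = c(f3 = 1.2), lapse = 0.05)
#' @export
observer_spec <- function(beta0 = 0, beta = c(f3 = 1), lapse = 0,
                          noise_sd = 0, id = NULL) {
  check_prob(lapse, "lapse")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  full <- c(f1 = 0, f2 = 0, f3 = 0, f4 = 0)
  if (length(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% names(full)))
      stop("'beta' must be named with feature ids f1..f4", call. = FALSE)
    full[names(beta)] <- beta
  }
  structure(list(beta0 = beta0, beta = full, lapse = lapse,
                 noise_sd = noise_sd, id = id),
            class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic observer%s: beta0 = %g, (%s), lapse = %g, noise_sd = %g\n",
    if (is.null(x$id)) "" else paste0(" ", x$id), x$beta0,
    paste(sprintf("%s = %g", names(x$beta), x$beta), collapse = ", "),
    x$lapse, x$noise_sd))
  invisible(x)
}

#' Simulate an observer's responses to a session
#'
#' Draws one stochastic RANDOM/DMS judgment per trial from the observer's
#' noisy weighted-feature rule.
#'
#' @param spec an \code{\link{observer_spec}}.
#' @param session a \code{\link{build_session}} data frame (or sequences).
#' @param seed optional integer seed.
#' @return data frame with columns \code{trial}, \code{response} (factor
#'   RANDOM/DMS) and \code{observer}.
#' @export
simulate_observer <- function(spec, session, seed = NULL) {
  stopifnot(inherits(spec, "observer_spec"))
  if (!is.null(seed)) set.seed(seed)
  X <- feature_matrix(session, 1:4)
  n <- nrow(X)
  eta <- spec$beta0 + drop(X %*% spec$beta)
  if (spec$noise_sd > 0) eta <- eta + stats::rnorm(n, 0, spec$noise_sd)
  p <- spec$lapse / 2 + (1 - spec$lapse) * stats::plogis(eta)
  r <- stats::rbinom(n, 1L, p)
  data.frame(trial = seq_len(n),
             response = factor(ifelse(r == 1L, "DMS", "RANDOM"),
                               levels = c("RANDOM", "DMS")),
             observer = if (is.null(spec$id)) NA_character_ else spec$id,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of observers
#'
#' Gives each observer a fresh session (sequences generated anew per trial,
#' as in the study) and simulates their responses. The study assigned
#' 33, 19 and 40 observers to the LD, MD and HD conditions respectively.
#'
#' @param specs list of \code{\link{observer_spec}} objects.
#' @param condition,n_trials,p_r,p_d,n session design, as in
#'   \code{\link{build_session}}.
#' @param seed optional integer master seed; observer-level seeds are
#'   derived from it.
#' @return a list of class \code{"dms_cohort"}: for each observer, a list
#'   with \code{spec}, \code{session}, \code{responses}.
#' @export
simulate_cohort <- function(specs, condition = "LD", n_trials = 100L,
                            p_r = NULL, p_d = NULL, n = NULL, seed = NULL) {
  if (!length(specs)) stop("need at least one observer spec", call. = FALSE)
  if (inherits(specs, "observer_spec")) specs <- list(specs)
  if (!is.null(seed)) set.seed(seed)
  base <- if (is.null(seed)) sample.int(2^30, 1L) else as.integer(seed)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s_seed <- (abs(base) + 69621 * i) %% 2147483647L
    session <- build_session(condition, n_trials, p_r, p_d, n, seed = s_seed)
    responses <- simulate_observer(specs[[i]], session,
                                   seed = s_seed + 1L)
    out[[i]] <- list(spec = specs[[i]], session = session,
                     responses = responses)
  }
  names(out) <- vapply(seq_along(specs), function(i) {
    id <- specs[[i]]$id
    if (is.null(id)) sprintf("obs%02d", i) else id
  }, "")
  class(out) <- "dms_cohort"
  out
}

#' @export
print.dms_cohort <- function(x, ...) {
  p <- attr(x[[1L]]$session, "params")
  cat(sprintf("Cohort of %d synthetic observers (%d trials each, p_r = %g, p_d = %g)\n",
              length(x), p$n_trials, p$p_r, p$p_d))
  invisible(x)
}
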