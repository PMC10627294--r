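# Classifiers for the pattern-detection task. Both are S3 objects with a
# predict() method mapping sequences to RANDOM/DMS decisions, and both
# support exact performance by complete enumeration of the 2^n sequence
# space as well as Monte Carlo performance.

#' Full Bayesian ideal observer
#'
#' The full model computes the posterior odds \eqn{\lambda} that a sequence
#' came from the DMS rather than the random generator and responds DMS
#' whenever \eqn{\lambda} exceeds the criterion (1 for the accuracy-
#' maximizing rule with equiprobable generators). Its sensitivity is an
#' upper bound for any observer of the task.
#'
#' @param p_r,p_d generator parameters of the condition.
#' @param n sequence length (20 in the study).
#' @param criterion likelihood-ratio criterion L > 0; ties go to RANDOM.
#' @return an object of class \code{c("ideal_observer", "dms_classifier")}.
#' @examples
#' io <- ideal_observer(p_d = 0.1)
#' predict(io, c("11111111110111111111", "01101001100101101001"))
#' @export
ideal_observer <- function(p_r = 0.9, p_d = 0.1, n = 20L, criterion = 1) {
  check_prob(p_r, "p_r"); check_prob(p_d, "p_d")
  if (criterion <= 0) stop("'criterion' must be positive", call. = FALSE)
  structure(list(p_r = p_r, p_d = p_d, n = check_length(n),
                 criterion = criterion, label = "full BDT model"),
            class = c("ideal_observer", "dms_classifier"))
}

#' @export
predict.ideal_observer <- function(object, newdata, ...) {
  posterior_odds(newdata, object$p_r, object$p_d, object$criterion)$decision
}

#' @export
print.dms_classifier <- function(x, ...) {
  cat(sprintf("%s: p_r = %g, p_d = %g, n = %d\n",
              x$label, x$p_r, x$p_d, x$n))
  invisible(x)
}

#' Exact distribution of a feature under both generators
#'
#' Enumerates all \code{2^n} sequences and accumulates, for each feature
#' value v, the total probability of sequences with that value under the
#' random generator (uniform, \code{2^-n} each) and under the DMS generator
#' (forward-recursion likelihoods).
#'
#' @param feature \code{"f1"}, \code{"f2"}, \code{"f3"} or \code{"f4"}
#'   (f2 is the sign-flipped longest alternation).
#' @inheritParams ideal_observer
#' @return an object of class \code{"feature_distribution"}: a list with
#'   \code{support} (sorted distinct values), \code{p_random}, \code{p_dms}
#'   (probability vectors summing to 1) and the parameters.
#' @export
exact_feature_distribution <- function(feature = c("f1", "f2", "f3", "f4"),
                                       p_r = 0.9, p_d = 0.1, n = 20L) {
  feature <- match.arg(feature)
  n <- check_enum(n)
  fv <- enum_feature(feature, n)
  # at p_d = 0.5 the DMS marginal is exactly uniform; bypass exp() so the
  # collapse limit compares equal to p_random without roundoff
  p_dms_seq <- if (p_d == 0.5) rep(1 / 2^n, 2^n) else
    exp(enum_log_dms(n, p_r, p_d))
  f <- factor(fv)
  support <- as.numeric(levels(f))
  p_dms <- as.numeric(rowsum(p_dms_seq, f, reorder = TRUE))
  p_random <- as.numeric(tabulate(f)) / 2^n
  structure(list(feature = feature, support = support,
                 p_random = p_random, p_dms = p_dms,
                 p_r = p_r, p_d = p_d, n = n),
            class = "feature_distribution")
}

#' @export
print.feature_distribution <- function(x, ...) {
  cat(sprintf("Exact distribution of %s (n = %d, p_r = %g, p_d = %g)\n",
              x$feature, x$n, x$p_r, x$p_d))
  print(data.frame(value = x$support, p_random = x$p_random,
                   p_dms = x$p_dms))
  invisible(x)
}

#' Ideal single-feature observer
#'
#' A classifier that sees only one feature of the sequence but uses it
#' optimally: it responds DMS at feature value v exactly when
#' \eqn{P[v \mid \mathrm{DMS}] > P[v \mid \mathrm{RANDOM}]} (the
#' likelihood-ratio rule on the feature's exact distribution; ties go to
#' RANDOM). For features with monotone likelihood ratio this reduces to a
#' fixed threshold on the feature value.
#'
#' @inheritParams exact_feature_distribution
#' @return an object of class \code{c("feature_observer",
#'   "dms_classifier")} containing the feature distribution and the set of
#'   feature values mapped to a DMS response.
#' @examples
#' fo <- feature_observer("f3", p_d = 0.1)
#' predict(fo, "11111111110000000000")
#' @export
feature_observer <- function(feature = c("f1", "f2", "f3", "f4"),
                             p_r = 0.9, p_d = 0.1, n = 20L) {
  feature <- match.arg(feature)
  dist <- exact_feature_distribution(feature, p_r, p_d, n)
  structure(list(feature = feature, dist = dist,
                 dms_values = dist$support[dist$p_dms > dist$p_random],
                 p_r = p_r, p_d = p_d, n = as.integer(n),
                 label = sprintf("ideal %s observer", feature)),
            class = c("feature_observer", "dms_classifier"))
}

#' @export
predict.feature_observer <- function(object, newdata, ...) {
  v <- as.numeric(feature_matrix(newdata,
                                 as.integer(substring(object$feature, 2L))))
  if (!all(v %in% object$dist$support))
    stop("feature value outside the distribution's support", call. = FALSE)
  factor(ifelse(v %in% object$dms_values, "DMS", "RANDOM"),
         levels = c("RANDOM", "DMS"))
}

#' Exact classifier performance by complete enumeration
#'
#' Enumerates every length-n sequence and accumulates the hit rate (DMS
#' responses weighted by DMS-generator probability) and false-alarm rate
#' (DMS responses weighted by the uniform random-generator probability),
#' then converts them to equal-variance Gaussian sensitivity d' and
#' criterion c. No extreme-rate correction is needed: the rates are interior
#' by construction except in degenerate limits.
#'
#' @param object a classifier (\code{\link{ideal_observer}} or
#'   \code{\link{feature_observer}}).
#' @return an \code{\link{sdt_estimate}} with exact hit and false-alarm
#'   rates.
#' @examples
#' exact_performance(ideal_observer(p_d = 0.1))
#' @export
exact_performance <- function(object) {
  UseMethod("exact_performance")
}

#' @export
exact_performance.ideal_observer <- function(object) {
  n <- check_enum(object$n)
  lp <- enum_log_dms(n, object$p_r, object$p_d)
  dms <- (lp + n * log(2)) > log(object$criterion)
  hit <- sum(exp(lp)[dms])
  fa <- sum(dms) / 2^n
  sdt_from_rates(hit, fa, n_signal = NA_integer_, n_noise = NA_integer_)
}

#' @export
exact_performance.feature_observer <- function(object) {
  d <- object$dist
  dms <- d$support %in% object$dms_values
  sdt_from_rates(sum(d$p_dms[dms]), sum(d$p_random[dms]),
                 n_signal = NA_integer_, n_noise = NA_integer_)
}

#' Monte Carlo classifier performance
#'
#' Simulates \code{n_reps} fresh sequences from each generator, applies the
#' classifier, and estimates hit and false-alarm rates and d' empirically
#' (extreme rates corrected by the 1/(2N) rule). The study's model contours
#' used 5,000 replications per point.
#'
#' @inheritParams exact_performance
#' @param n_reps replications per generator.
#' @param seed optional integer seed.
#' @return an \code{\link{sdt_estimate}}.
#' @export
mc_performance <- function(object, n_reps = 5000L, seed = NULL) {
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sig <- generate_dms(n_reps, object$n, object$p_r, object$p_d)
  noi <- generate_random(n_reps, object$n)
  hits <- sum(predict(object, sig) == "DMS")
  fas <- sum(predict(object, noi) == "DMS")
  sdt_from_counts(hits, n_reps - hits, fas, n_reps - fas)
}
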