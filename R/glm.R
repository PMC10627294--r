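# Logistic feature-combination models. An observer's per-trial judgments
# are regressed on a subset of the four pattern features:
#
#   E[P(respond DMS | S)] = psi(beta0 + sum_k beta_k * f_k(S)),
#
# psi the logistic function. Fitting is maximum likelihood (IRLS via
# stats::glm). Weights are also reported in Menard's fully standardized
# form so they are comparable across features and observers, and each fit
# carries its small-sample corrected AIC for model comparison.

#' Fit a logistic feature-combination model
#'
#' Maximum-likelihood logistic regression of an observer's binary judgments
#' (DMS = 1) on a subset of the four pattern features, with intercept. The
#' fit stores raw weights, Menard fully standardized weights, the maximized
#' log-likelihood and the AICc.
#'
#' Complete or quasi-complete separation (an observer whose responses are a
#' deterministic function of the features) is detected and flagged; the
#' reported weights are then the large-but-finite values where IRLS stopped,
#' and the log-likelihood is essentially 0.
#'
#' @param responses per-trial judgments: a factor/character vector of
#'   \code{"RANDOM"}/\code{"DMS"}, a 0/1 vector, or a data frame with a
#'   \code{response} column.
#' @param data the stimuli: a session data frame, sequences, or a
#'   precomputed feature matrix with columns among \code{f1..f4}
#'   (see \code{\link{feature_matrix}}).
#' @param subset integer ids of the features to include, e.g. \code{c(1, 3)}.
#' @return an object of class \code{"feature_glm"} with components
#'   \code{coefficients}, \code{beta_std}, \code{loglik}, \code{aicc},
#'   \code{k_params}, \code{n_obs}, \code{subset}, \code{model_id},
#'   \code{separation}, \code{fitted}, \code{glm}.
#' @examples
#' set.seed(42)
#' s <- build_session("LD", n_trials = 100, seed = 42)
#' obs <- observer_spec(beta0 = -14, beta = c(f3 = 1.2), lapse = 0.05)
#' r <- simulate_observer(obs, s, seed = 1)
#' fit <- feature_glm(r, s, subset = c(1, 3))
#' summary(fit)
#' @export
feature_glm <- function(responses, data, subset = 1:4) {
  y <- coerce_responses(responses)
  X <- coerce_features(data, subset)
  subset <- sort(unique(as.integer(subset)))
  if (length(y) != nrow(X))
    stop("responses and stimuli have different lengths", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("need at least one trial in each response class", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("rank deficiency: constant feature column (%s)",
                 paste(colnames(X)[sds == 0], collapse = ", ")),
         call. = FALSE)
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  p <- stats::fitted(fit)
  separation <- all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6)
  if (separation)
    warning("complete separation: responses are a deterministic function ",
            "of the features; weights are capped at the IRLS stopping point",
            call. = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  n <- length(y)
  out <- structure(list(
    coefficients = stats::coef(fit),
    subset = subset,
    model_id = paste0(subset, collapse = ""),
    loglik = ll,
    k_params = k,
    n_obs = n,
    aicc = aicc(ll, k, n),
    separation = separation,
    fitted = p,
    y = y,
    feature_sd = sds,
    glm = fit), class = "feature_glm")
  out$beta_std <- standardize_menard(out)
  out
}

coerce_responses <- function(responses) {
  if (is.data.frame(responses)) responses <- responses$response
  if (is.factor(responses)) responses <- as.character(responses)
  if (is.character(responses)) {
    if (!all(responses %in% c("RANDOM", "DMS")))
      stop("responses must be 'RANDOM' or 'DMS'", call. = FALSE)
    return(as.integer(responses == "DMS"))
  }
  r <- as.integer(responses)
  if (anyNA(r) || !all(r %in% 0:1))
    stop("responses must be binary", call. = FALSE)
  r
}

coerce_features <- function(data, subset) {
  subset <- sort(unique(as.integer(subset)))
  want <- paste0("f", subset)
  if (is.matrix(data) && !is.null(colnames(data)) &&
      all(want %in% colnames(data)))
    return(data[, want, drop = FALSE])
  feature_matrix(data, subset)
}

#' Menard fully standardized logistic regression weights
#'
#' Standardizes the raw weights of a fitted logistic model as
#' \deqn{\beta^*_k = \beta_k \, s_{x_k} \, R / s_{\hat\eta},}
#' where \eqn{s_{x_k}} is the sample SD of feature k, \eqn{s_{\hat\eta}} the
#' sample SD of the fitted linear predictor, and R the correlation between
#' fitted probabilities and observed responses. A one-SD change in the
#' feature then changes the predicted logit by \eqn{\beta^*_k} standard
#' deviations, making weights comparable across features of different scales
#' and across observers.
#'
#' @param fit a \code{\link{feature_glm}} object.
#' @return named numeric vector of standardized weights (no intercept).
#' @export
standardize_menard <- function(fit) {
  stopifnot(inherits(fit, "feature_glm"))
  beta <- fit$coefficients[-1L]
  sds <- fit$feature_sd
  if (any(sds == 0))
    stop("standardization undefined for a zero-variance predictor",
         call. = FALSE)
  eta <- stats::qlogis(pmin(pmax(fit$fitted, 1e-12), 1 - 1e-12))
  s_eta <- stats::sd(eta)
  R <- suppressWarnings(stats::cor(fit$fitted, fit$y))
  if (!is.finite(R)) R <- 0
  out <- beta * sds * R / s_eta
  names(out) <- names(beta)
  out
}

#' Dominant feature of an observer
#'
#' The feature with the largest fully standardized weight in a four-feature
#' fit. Because the longest-alternation feature enters models sign-flipped,
#' all generative weights are expected positive and the signed argmax is
#' used. Ties are broken toward the lowest feature index and flagged; a fit
#' whose standardized weights are all negligible is flagged unreliable.
#'
#' @param fit a \code{\link{feature_glm}} fitted with all four features.
#' @param tol weights within \code{tol} of the maximum count as tied.
#' @return the dominant feature id (\code{"f1".."f4"}) with attributes
#'   \code{tie} (exact tie, broken toward the lowest index) and
#'   \code{reliable} (FALSE when the winning feature's raw weight is not
#'   distinguishable from zero at |z| >= 2, as for a guessing observer).
#' @export
dominant_feature <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "feature_glm"))
  if (length(fit$subset) != 4L)
    stop("dominant feature requires the four-feature fit", call. = FALSE)
  w <- fit$beta_std
  best <- which.max(w)  # first maximum = lowest feature index
  tie <- sum(w >= w[best] - tol) > 1L
  z <- summary(fit$glm)$coefficients[, "z value"][-1L]
  structure(names(w)[best], tie = tie,
            reliable = is.finite(z[best]) && abs(z[best]) >= 2)
}

# ---- methods --------------------------------------------------------------

#' @export
print.feature_glm <- function(x, digits = 4, ...) {
  cat(sprintf("Feature GLM '%s' (%d trials): logLik = %.*f, AICc = %.*f%s\n",
              x$model_id, x$n_obs, digits, x$loglik, digits, x$aicc,
              if (x$separation) " [separation]" else ""))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.feature_glm <- function(object, ...) {
  s <- summary(object$glm)
  tab <- s$coefficients
  std <- c(NA_real_, object$beta_std)
  out <- cbind(tab, beta_std = std)
  structure(list(model_id = object$model_id, coefficients = out,
                 loglik = object$loglik, aicc = object$aicc,
                 n_obs = object$n_obs, separation = object$separation),
            class = "summary.feature_glm")
}

#' @export
print.summary.feature_glm <- function(x, ...) {
  cat(sprintf("Feature GLM '%s' on %d trials\n", x$model_id, x$n_obs))
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE, P.values = TRUE,
                      na.print = "")
  cat(sprintf("logLik = %.4f, AICc = %.4f%s\n", x$loglik, x$aicc,
              if (x$separation) " [complete separation]" else ""))
  invisible(x)
}

#' @export
coef.feature_glm <- function(object, standardized = FALSE, ...) {
  if (standardized) object$beta_std else object$coefficients
}

#' @export
logLik.feature_glm <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
predict.feature_glm <- function(object, newdata = NULL,
                                type = c("prob", "response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(pmin(pmax(object$fitted, 1e-12), 1 - 1e-12))
    p <- object$fitted
  } else {
    X <- coerce_features(newdata, object$subset)
    eta <- drop(cbind(1, X) %*% object$coefficients)
    p <- stats::plogis(eta)
  }
  if (type == "link") return(eta)
  if (type == "response")
    return(factor(ifelse(p > 0.5, "DMS", "RANDOM"),
                  levels = c("RANDOM", "DMS")))
  p
}

#' @export
residuals.feature_glm <- function(object, ...) {
  stats::residuals(object$glm, ...)
}
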