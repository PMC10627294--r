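# Model comparison across feature subsets: small-sample corrected AIC,
# evidence ratios, and the 15-model table (all non-empty subsets of the
# four features).

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n - k - 1}}
#' where \eqn{\ell} is the maximized log-likelihood, k the number of free
#' parameters and n the number of observations. Converges to plain AIC as n
#' grows; lower is better.
#'
#' @param loglik maximized log-likelihood.
#' @param k_params number of free parameters (features + intercept).
#' @param n_obs number of observations (trials).
#' @return the AICc value.
#' @examples
#' aicc(-50, 3, 100)  # 106.25
#' @export
aicc <- function(loglik, k_params, n_obs) {
  if (n_obs <= k_params + 1)
    stop("AICc undefined: need n_obs > k_params + 1", call. = FALSE)
  -2 * loglik + 2 * k_params + 2 * k_params * (k_params + 1) /
    (n_obs - k_params - 1)
}

#' Evidence ratio between two models
#'
#' \code{exp(delta_aicc / 2)}: the relative likelihood, in a
#' Kullback-Leibler sense, that the lower-AICc model of a pair is to be
#' preferred. A ratio above 3 is substantial evidence, above 10 strong,
#' above 30 very strong and above 100 decisive (Jeffreys' levels).
#'
#' @param delta_aicc AICc difference (other minus best for ratios >= 1;
#'   signed input is allowed).
#' @return the evidence ratio.
#' @examples
#' evidence_ratio(2 * log(10))  # 10
#' @export
evidence_ratio <- function(delta_aicc) exp(delta_aicc / 2)

#' Enumerate feature subsets
#'
#' All non-empty subsets of the features, ordered by size then
#' lexicographically, named by concatenated indices (\code{"13"} is the
#' model using F1 and F3). Four features give 15 models: four single-
#' feature, six two-feature, four three-feature and the full four-feature
#' model.
#'
#' @param n_features number of candidate features.
#' @return named list of integer vectors.
#' @examples
#' names(enumerate_subsets(4))
#' @export
enumerate_subsets <- function(n_features = 4L) {
  if (n_features < 1) stop("'n_features' must be >= 1", call. = FALSE)
  out <- list()
  for (size in seq_len(n_features)) {
    combs <- utils::combn(n_features, size, simplify = FALSE)
    out <- c(out, combs)
  }
  names(out) <- vapply(out, paste0, "", collapse = "")
  out
}

#' Fit all feature-subset models for one observer
#'
#' Fits the logistic feature-combination model for every non-empty subset of
#' the four features (15 models) on one observer's trials.
#'
#' @inheritParams feature_glm
#' @return a named list of \code{\link{feature_glm}} fits, class
#'   \code{"feature_glm_set"}.
#' @export
fit_all_models <- function(responses, data) {
  X <- coerce_features(data, 1:4)
  fits <- lapply(enumerate_subsets(4L), function(s)
    feature_glm(responses, X, subset = s))
  class(fits) <- "feature_glm_set"
  fits
}

#' @export
print.feature_glm_set <- function(x, ...) {
  cat(sprintf("%d fitted feature GLMs\n", length(x)))
  print(multimodel_table(x))
  invisible(x)
}

#' Multimodel comparison table
#'
#' Ranks a complete set of feature-subset fits by AICc, computes each
#' model's AICc difference and evidence ratio against the best model, and
#' marks the supported set: models whose evidence ratio against the best
#' does not exceed the criterion (default 10, strong evidence in Jeffreys'
#' terms). Also reports the parsimony ladder: the best model of each size
#' and the evidence ratio of each best k-feature model against the best
#' (k+1)-feature model.
#'
#' @param fits a \code{\link{fit_all_models}} result, or a list of them
#'   (one per observer), in which case log-likelihood and AICc are averaged
#'   across observers per subset before ranking.
#' @param criterion evidence-ratio cutoff (3, 10, 30 or 100 are the usual
#'   Jeffreys levels).
#' @return a data frame of class \code{"model_table"} with columns
#'   \code{model}, \code{k}, \code{loglik}, \code{aicc}, \code{delta_aicc},
#'   \code{evidence_ratio}, \code{supported}, sorted by AICc; the parsimony
#'   ladder is attached as attribute \code{"parsimony"}.
#' @export
multimodel_table <- function(fits, criterion = 10) {
  if (inherits(fits, "feature_glm_set")) {
    tab <- data.frame(
      model = vapply(fits, `[[`, "", "model_id"),
      k = vapply(fits, `[[`, 0, "k_params"),
      loglik = vapply(fits, `[[`, 0, "loglik"),
      aicc = vapply(fits, `[[`, 0, "aicc"),
      stringsAsFactors = FALSE)
  } else if (is.list(fits) && all(vapply(fits, inherits, TRUE,
                                         "feature_glm_set"))) {
    ids <- vapply(fits[[1L]], `[[`, "", "model_id")
    tab <- data.frame(
      model = ids,
      k = vapply(fits[[1L]], `[[`, 0, "k_params"),
      loglik = rowMeans(vapply(fits, function(f)
        vapply(f, `[[`, 0, "loglik"), numeric(length(ids)))),
      aicc = rowMeans(vapply(fits, function(f)
        vapply(f, `[[`, 0, "aicc"), numeric(length(ids)))),
      stringsAsFactors = FALSE)
  } else {
    stop("'fits' must be a feature_glm_set or a list of them", call. = FALSE)
  }
  expected <- names(enumerate_subsets(4L))
  if (!setequal(tab$model, expected))
    stop("incomplete table: need one fit per feature subset", call. = FALSE)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$evidence_ratio <- evidence_ratio(tab$delta_aicc)
  tab$supported <- tab$evidence_ratio <= criterion
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL

  size <- nchar(tab$model)
  sizes <- sort(unique(size))
  best <- do.call(rbind, lapply(sizes, function(s) {
    sub <- tab[size == s, ]
    sub[which.min(sub$aicc), c("model", "k", "aicc")]
  }))
  best$size <- sizes
  # evidence ratio of best k-feature model against best (k+1)-feature model
  best$er_vs_next <- c(evidence_ratio(best$aicc[-nrow(best)] -
                                        best$aicc[-1L]), NA_real_)
  attr(tab, "parsimony") <- best[, c("size", "model", "aicc", "er_vs_next")]
  attr(tab, "criterion") <- criterion
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' @export
print.model_table <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison (evidence-ratio criterion %g)\n",
              attr(x, "criterion")))
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, digits)
  df$aicc <- round(df$aicc, digits)
  df$delta_aicc <- round(df$delta_aicc, digits)
  df$evidence_ratio <- signif(df$evidence_ratio, digits)
  print.data.frame(df)
  cat("\nBest model per size (er_vs_next: evidence ratio vs best next-size model)\n")
  p <- attr(x, "parsimony")
  p$aicc <- round(p$aicc, digits)
  p$er_vs_next <- signif(p$er_vs_next, digits)
  print.data.frame(p, row.names = FALSE)
  invisible(x)
}
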