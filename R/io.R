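# Session files and the end-to-end pipeline. Sessions round-trip through a
# CSV (trial, sequence, true_label) plus a JSON sidecar holding the
# generator parameters, so data stay human-inspectable.

#' Write a session to disk
#'
#' Writes the trials as CSV (\code{trial,sequence,true_label}) and the
#' generator parameters as a JSON sidecar at \code{<path>.json}.
#'
#' @param session a \code{\link{build_session}} data frame.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "dms_session"))
  utils::write.csv(session[, c("trial", "sequence", "true_label")],
                   path, row.names = FALSE, quote = FALSE)
  p <- attr(session, "params")
  jsonlite::write_json(p[c("p_r", "p_d", "n", "n_trials", "seed")],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a session from disk
#'
#' Reads a session CSV and its JSON sidecar, validating every row: the
#' sequence must be a 0/1 string of the sidecar's length n and the label
#' RANDOM or DMS. Malformed rows are reported by line.
#'
#' @param path CSV file path (sidecar expected at \code{<path>.json}).
#' @return a \code{"dms_session"} data frame.
#' @export
read_session <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar JSON: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (k in c("p_r", "p_d", "n", "n_trials"))
    if (is.null(meta[[k]]))
      stop(sprintf("sidecar is missing '%s'", k), call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(trial = "integer",
                                             sequence = "character",
                                             true_label = "character"))
  bad_len <- which(nchar(df$sequence) != meta$n)
  if (length(bad_len))
    stop(sprintf("sequence of wrong length at row(s) %s (expected %d tokens)",
                 paste(bad_len, collapse = ", "), meta$n), call. = FALSE)
  bad_tok <- which(!grepl("^[01]+$", df$sequence))
  if (length(bad_tok))
    stop(sprintf("non-binary tokens at row(s) %s",
                 paste(bad_tok, collapse = ", ")), call. = FALSE)
  bad_lab <- which(!df$true_label %in% c("RANDOM", "DMS"))
  if (length(bad_lab))
    stop(sprintf("invalid label at row(s) %s",
                 paste(bad_lab, collapse = ", ")), call. = FALSE)
  attr(df, "params") <- list(p_r = meta$p_r, p_d = meta$p_d,
                             n = as.integer(meta$n),
                             n_trials = as.integer(meta$n_trials),
                             seed = meta$seed)
  class(df) <- c("dms_session", "data.frame")
  df
}

#' Run the full analysis pipeline
#'
#' End to end for a cohort of synthetic observers in one condition:
#' simulate sessions and responses, extract features, fit all 15 feature-
#' subset GLMs per observer, build the multimodel comparison table, score
#' each observer's sensitivity and efficiency against the exact full-model
#' d', and identify dominant features. Fully reproducible from the seed.
#'
#' @param condition \code{"LD"}, \code{"MD"} or \code{"HD"}.
#' @param specs list of \code{\link{observer_spec}}; default is a small
#'   illustrative cohort of mixed feature users.
#' @param n_trials trials per observer session.
#' @param seed integer master seed.
#' @param criterion evidence-ratio cutoff for the model table.
#' @param out_dir optional directory; when given, per-observer sessions,
#'   responses and the report JSON are written there.
#' @return a list of class \code{"dms_report"}: \code{condition},
#'   \code{full_model} (exact SDT of the ideal observer),
#'   \code{observers} (per observer: d', efficiency, dominant feature,
#'   best model), \code{model_table} (AICc averaged across observers).
#' @export
run_pipeline <- function(condition = "LD", specs = NULL, n_trials = 100L,
                         seed = 1L, criterion = 10, out_dir = NULL) {
  cond <- condition_params(condition)
  if (is.null(specs))
    specs <- list(
      observer_spec(-10, c(f3 = 0.8), lapse = 0.05, id = "f3-user"),
      observer_spec(-3, c(f1 = 0.5), lapse = 0.05, id = "f1-user"),
      observer_spec(-8, c(f1 = 0.3, f3 = 0.5), lapse = 0.1, id = "f1f3-user"),
      observer_spec(0, lapse = 1, id = "guesser"))
  cohort <- simulate_cohort(specs, condition, n_trials, seed = seed)
  full <- exact_performance(ideal_observer(cond$p_r, cond$p_d, cond$n))
  fit_sets <- vector("list", length(cohort))
  obs_rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    ob <- cohort[[i]]
    fits <- fit_all_models(ob$responses, ob$session)
    fit_sets[[i]] <- fits
    sdt <- score_session(ob$responses, ob$session)
    tab <- multimodel_table(fits, criterion)
    dom <- dominant_feature(fits[["1234"]])
    obs_rows[[i]] <- data.frame(
      observer = names(cohort)[i],
      d_prime = sdt$d_prime,
      efficiency = sdt$d_prime / full$d_prime,
      dominant = as.character(dom),
      dominant_reliable = attr(dom, "reliable"),
      best_model = tab$model[1L],
      stringsAsFactors = FALSE)
  }
  observers <- do.call(rbind, obs_rows)
  report <- structure(list(
    condition = cond,
    n_trials = n_trials,
    seed = seed,
    full_model = full,
    observers = observers,
    model_table = multimodel_table(fit_sets, criterion)),
    class = "dms_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(cohort)) {
      write_session(cohort[[i]]$session,
                    file.path(out_dir, sprintf("session_%s.csv",
                                               names(cohort)[i])))
      utils::write.csv(cohort[[i]]$responses,
                       file.path(out_dir, sprintf("responses_%s.csv",
                                                  names(cohort)[i])),
                       row.names = FALSE)
    }
    jsonlite::write_json(list(
      condition = cond, seed = seed,
      full_model = report$full_model[c("hit_rate", "fa_rate", "d_prime",
                                       "criterion_c")],
      observers = observers,
      model_table = as.data.frame(report$model_table)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.dms_report <- function(x, ...) {
  cat(sprintf("Pipeline report: condition %s (p_d = %g), %d observers, seed %d\n",
              x$condition$condition, x$condition$p_d, nrow(x$observers),
              x$seed))
  cat(sprintf("Full BDT model (exact): d' = %.4f\n", x$full_model$d_prime))
  print.data.frame(x$observers, row.names = FALSE, digits = 4)
  invisible(x)
}
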