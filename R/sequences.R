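# Internal: coerce sequences to an integer 0/1 matrix, one sequence per row.
# Accepts a character vector of "0"/"1" strings, a single 0/1 vector, a 0/1
# matrix, or a session data frame with a `sequence` column.
as_token_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (is.null(x$sequence))
      stop("data frame input must have a 'sequence' column", call. = FALSE)
    x <- as.character(x$sequence)
  }
  if (is.character(x)) {
    nch <- nchar(x)
    if (length(x) == 0L) stop("no sequences supplied", call. = FALSE)
    if (length(unique(nch)) != 1L)
      stop("sequences have unequal lengths", call. = FALSE)
    m <- matrix(as.integer(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)),
                nrow = length(x), ncol = nch[1L], byrow = TRUE)
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "integer"
  } else if (is.numeric(x) || is.logical(x)) {
    m <- matrix(as.integer(x), nrow = 1L)
  } else {
    stop("cannot interpret input as token sequences", call. = FALSE)
  }
  if (ncol(m) < 1L) stop("sequences must have length >= 1", call. = FALSE)
  if (anyNA(m) || !all(m == 0L | m == 1L))
    stop("tokens must all be 0 (yellow) or 1 (blue)", call. = FALSE)
  m
}

# Internal: matrix of sequences -> character vector of 0/1 strings
tokens_to_string <- function(m) {
  m <- as_token_matrix(m)
  apply(m, 1L, paste0, collapse = "")
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(p)
}

check_length <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("sequence length 'n' must be a positive integer", call. = FALSE)
  as.integer(n)
}

#' Study conditions
#'
#' The three disruption conditions of the pattern-detection task: low (LD),
#' medium (MD) and high (HD) disruption, all with repetition probability
#' \code{p_r = 0.9} and disruption probability \code{p_d} of 0.1, 0.2 and 0.3
#' respectively, on sequences of 20 tokens.
#'
#' @param condition one of \code{"LD"}, \code{"MD"}, \code{"HD"}.
#' @return a list with elements \code{p_r}, \code{p_d}, \code{n}.
#' @examples
#' condition_params("MD")
#' @export
condition_params <- function(condition = c("LD", "MD", "HD")) {
  condition <- match.arg(condition)
  p_d <- c(LD = 0.1, MD = 0.2, HD = 0.3)[[condition]]
  list(condition = condition, p_r = 0.9, p_d = p_d, n = 20L)
}

#' Generate random binary sequences
#'
#' Each token is an independent fair Bernoulli draw (equally likely blue = 1
#' or yellow = 0), the "fair coin" generator of the task.
#'
#' @param n_seq number of sequences to generate.
#' @param n tokens per sequence (20 in the study).
#' @return integer 0/1 matrix with \code{n_seq} rows; a single sequence is
#'   returned as a 1-row matrix.
#' @examples
#' set.seed(1)
#' generate_random(2, n = 20)
#' @export
generate_random <- function(n_seq = 1L, n = 20L) {
  n <- check_length(n)
  matrix(sample(0:1, n_seq * n, replace = TRUE), nrow = n_seq, ncol = n)
}

#' Generate Markov sequences
#'
#' The leftmost token is equally likely blue or yellow; each subsequent token
#' repeats the color of its left neighbor with probability \code{p_r}.
#'
#' @inheritParams generate_random
#' @param p_r repetition probability in [0, 1].
#' @return integer 0/1 matrix with \code{n_seq} rows.
#' @export
generate_markov <- function(n_seq = 1L, n = 20L, p_r = 0.9) {
  n <- check_length(n)
  check_prob(p_r, "p_r")
  m <- matrix(0L, nrow = n_seq, ncol = n)
  m[, 1L] <- sample(0:1, n_seq, replace = TRUE)
  if (n > 1L) for (t in 2:n) {
    stay <- stats::runif(n_seq) < p_r
    m[, t] <- ifelse(stay, m[, t - 1L], 1L - m[, t - 1L])
  }
  m
}

#' Disrupt a sequence
#'
#' Independently flips each token (blue to yellow or vice versa) with
#' probability \code{p_d}, the disruption probability. Disruption plays the
#' role of noise in signal detection terms.
#'
#' @param x sequences (matrix, 0/1 vector, or character strings).
#' @param p_d per-token flip probability in [0, 1].
#' @return integer 0/1 matrix of the same dimensions.
#' @export
disrupt <- function(x, p_d) {
  m <- as_token_matrix(x)
  check_prob(p_d, "p_d")
  flip <- matrix(stats::runif(length(m)) < p_d, nrow = nrow(m))
  m[flip] <- 1L - m[flip]
  m
}

#' Generate disrupted Markov sequences (DMS)
#'
#' A DMS is produced in two stages: generate a Markov sequence with
#' repetition probability \code{p_r}, then independently flip each token with
#' probability \code{p_d}. At \code{p_d = 0.5} the output is statistically
#' indistinguishable from the random generator.
#'
#' @inheritParams generate_markov
#' @param p_d disruption probability in [0, 1].
#' @return integer 0/1 matrix with \code{n_seq} rows.
#' @export
generate_dms <- function(n_seq = 1L, n = 20L, p_r = 0.9, p_d = 0.1) {
  disrupt(generate_markov(n_seq, n, p_r), p_d)
}

#' Build an experimental session
#'
#' A session is a sequence of trials, half generated by the random generator
#' and half by the DMS generator, presented in randomized order (the study
#' used 100 trials, 50 of each). Sequences are generated anew for every
#' trial. With \code{balanced = FALSE} the generator is instead chosen by a
#' fair coin flip on each trial, so the split is only balanced in
#' expectation.
#'
#' @param condition \code{"LD"}, \code{"MD"} or \code{"HD"}; ignored when
#'   \code{p_d} is given explicitly.
#' @param n_trials number of trials; must be even when \code{balanced}.
#' @param p_r,p_d,n generator parameters, defaulting to the chosen condition.
#' @param seed optional integer master seed. Per-trial seeds are derived from
#'   it deterministically and recorded, so any single trial can be
#'   regenerated in isolation.
#' @param balanced enforce an exact half/half label split (the study design).
#' @return a data frame of class \code{"dms_session"} with columns
#'   \code{trial}, \code{sequence} (0/1 string), \code{true_label}
#'   (\code{"RANDOM"}/\code{"DMS"}) and \code{trial_seed}; generator
#'   parameters are attached as the \code{"params"} attribute.
#' @examples
#' s <- build_session("LD", n_trials = 10, seed = 7)
#' table(s$true_label)
#' @export
build_session <- function(condition = c("LD", "MD", "HD"), n_trials = 100L,
                          p_r = NULL, p_d = NULL, n = NULL, seed = NULL,
                          balanced = TRUE) {
  cond <- condition_params(match.arg(condition))
  if (is.null(p_r)) p_r <- cond$p_r
  if (is.null(p_d)) p_d <- cond$p_d
  if (is.null(n)) n <- cond$n
  n <- check_length(n)
  check_prob(p_r, "p_r"); check_prob(p_d, "p_d")
  if (n_trials < 1 || n_trials != round(n_trials))
    stop("'n_trials' must be a positive integer", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (balanced && n_trials %% 2L != 0L)
    stop("a balanced session needs an even number of trials", call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  if (balanced) {
    labels <- sample(rep(c("RANDOM", "DMS"), each = n_trials %/% 2L))
  } else {
    labels <- ifelse(stats::runif(n_trials) < 0.5, "DMS", "RANDOM")
  }
  # deterministic per-trial substreams from the master seed
  base <- if (is.null(seed)) sample.int(2^30, 1L) else as.integer(seed)
  trial_seed <- (abs(base) + 48271 * seq_len(n_trials)) %% 2147483647L
  seqs <- character(n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(trial_seed[i])
    m <- if (labels[i] == "DMS") generate_dms(1L, n, p_r, p_d)
         else generate_random(1L, n)
    seqs[i] <- tokens_to_string(m)
  }
  out <- data.frame(trial = seq_len(n_trials), sequence = seqs,
                    true_label = labels, trial_seed = trial_seed,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(p_r = p_r, p_d = p_d, n = n,
                              n_trials = n_trials, seed = seed,
                              balanced = balanced)
  class(out) <- c("dms_session", "data.frame")
  out
}

#' @export
print.dms_session <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Session: %d trials (%d DMS, %d RANDOM), n = %d, p_r = %g, p_d = %g\n",
    nrow(x), sum(x$true_label == "DMS"), sum(x$true_label == "RANDOM"),
    p$n, p$p_r, p$p_d))
  print.data.frame(utils::head(x, 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more trials\n", nrow(x) - 5L))
  invisible(x)
}
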