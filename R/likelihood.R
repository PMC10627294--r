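# Likelihoods under the two generators.
#
# The DMS generator is a two-state hidden Markov process: the hidden
# (undisrupted) chain starts fair and repeats its previous color with
# probability p_r; the observed token equals the hidden token with
# probability 1 - p_d. P[S | DMS] marginalizes over all 2^n hidden
# sequences, computed by the standard forward recursion with per-step
# rescaling so n = 20 (and far beyond) is numerically stable.

.dmsdt_cache <- new.env(parent = emptyenv())

# Internal: forward recursion over rows of a 0/1 matrix.
# Returns log P[S | DMS] for each row. p_d = 0.5 makes every emission
# uninformative, so the marginal is exactly uniform; that identity is applied
# directly to keep the collapse limit free of roundoff.
forward_log_dms <- function(m, p_r, p_d) {
  n <- ncol(m)
  if (p_d == 0.5) return(rep(-n * log(2), nrow(m)))
  b <- m[, 1L]
  # emission probabilities given hidden state 0 / 1; both expressions are
  # symmetric in b <-> 1 - b so color complement is invariant to the bit
  e0 <- (1 - p_d) * (1 - b) + p_d * b
  e1 <- (1 - p_d) * b + p_d * (1 - b)
  a0 <- 0.5 * e0
  a1 <- 0.5 * e1
  s <- a0 + a1
  lp <- log(s)
  s[s == 0] <- 1
  a0 <- a0 / s; a1 <- a1 / s
  if (n > 1L) for (t in 2:n) {
    b <- m[, t]
    e0 <- (1 - p_d) * (1 - b) + p_d * b
    e1 <- (1 - p_d) * b + p_d * (1 - b)
    t0 <- a0 * p_r + a1 * (1 - p_r)
    t1 <- a0 * (1 - p_r) + a1 * p_r
    a0 <- t0 * e0
    a1 <- t1 * e1
    s <- a0 + a1
    lp <- lp + log(s)
    s[s == 0] <- 1
    a0 <- a0 / s; a1 <- a1 / s
  }
  lp
}

#' Log-likelihood of sequences under the DMS generator
#'
#' Computes \eqn{\log P[S \mid \mathrm{DMS}]}, the probability that the
#' disrupted-Markov generator with parameters \code{p_r}, \code{p_d} produced
#' each sequence, marginalized over the unobserved undisrupted Markov
#' sequence (forward recursion in a two-state hidden chain).
#'
#' @param x sequences (0/1 matrix with one sequence per row, a single 0/1
#'   vector, character strings, or a session data frame).
#' @param p_r repetition probability of the underlying Markov chain.
#' @param p_d per-token disruption (flip) probability.
#' @return numeric vector of log-probabilities, one per sequence.
#' @examples
#' likelihood_dms("11111111110000000000", p_r = 0.9, p_d = 0.1)
#' @export
likelihood_dms <- function(x, p_r = 0.9, p_d = 0.1) {
  m <- as_token_matrix(x)
  check_prob(p_r, "p_r"); check_prob(p_d, "p_d")
  forward_log_dms(m, p_r, p_d)
}

#' Log-likelihood of sequences under the random generator
#'
#' The random generator draws each token independently with probability 0.5,
#' so every length-\code{n} sequence has probability \eqn{0.5^n}.
#'
#' @inheritParams likelihood_dms
#' @return numeric vector of log-probabilities (\code{-n * log(2)}).
#' @export
likelihood_random <- function(x) {
  m <- as_token_matrix(x)
  rep(-ncol(m) * log(2), nrow(m))
}

#' Posterior odds that a sequence is patterned
#'
#' Computes \eqn{\lambda = P[S|\mathrm{DMS}] / P[S|\mathrm{RANDOM}]}, the
#' posterior odds of DMS versus random when the two generators are
#' equiprobable (prior odds 1, the study design), and the normative
#' classification: respond DMS if and only if \eqn{\lambda > L}. The ideal
#' rule that maximizes accuracy has \eqn{L = 1}; ties resolve to RANDOM.
#'
#' @inheritParams likelihood_dms
#' @param criterion the likelihood-ratio criterion \eqn{L > 0}.
#' @return a data frame with columns \code{log_p_dms}, \code{log_p_random},
#'   \code{lambda} and \code{decision} (factor RANDOM/DMS).
#' @examples
#' posterior_odds("11111111111111111111", p_r = 0.9, p_d = 0.1)
#' @export
posterior_odds <- function(x, p_r = 0.9, p_d = 0.1, criterion = 1) {
  if (!is.numeric(criterion) || length(criterion) != 1L || criterion <= 0)
    stop("'criterion' must be a single positive number", call. = FALSE)
  m <- as_token_matrix(x)
  lpd <- likelihood_dms(m, p_r, p_d)
  lpr <- likelihood_random(m)
  lam <- exp(lpd - lpr)
  dec <- factor(ifelse(lpd - lpr > log(criterion), "DMS", "RANDOM"),
                levels = c("RANDOM", "DMS"))
  data.frame(log_p_dms = lpd, log_p_random = lpr, lambda = lam,
             decision = dec)
}

# ---- complete enumeration -------------------------------------------------

# All computations over the full sequence space represent the 2^n sequences
# implicitly by index 0..2^n-1; bit t-1 of the index is the token at
# position t. The enumeration cap keeps memory bounded.
.enum_cap <- 24L

check_enum <- function(n) {
  n <- check_length(n)
  if (n > .enum_cap)
    stop(sprintf("complete enumeration is limited to n <= %d (got n = %d)",
                 .enum_cap, n), call. = FALSE)
  n
}

enum_bit <- function(idx, t) {
  as.numeric(bitwAnd(idx, bitwShiftL(1L, t - 1L)) != 0L)
}

# log P[S | DMS] for every sequence index 0..2^n-1 (vectorized forward
# recursion across the whole space). Cached per (n, p_r, p_d).
enum_log_dms <- function(n, p_r, p_d) {
  n <- check_enum(n)
  key <- sprintf("lp_%d_%.17g_%.17g", n, p_r, p_d)
  if (!is.null(.dmsdt_cache[[key]])) return(.dmsdt_cache[[key]])
  idx <- 0:(2^n - 1L)
  if (p_d == 0.5) {
    lp <- rep(-n * log(2), length(idx))
  } else {
    b <- enum_bit(idx, 1L)
    e0 <- (1 - p_d) * (1 - b) + p_d * b
    e1 <- (1 - p_d) * b + p_d * (1 - b)
    a0 <- 0.5 * e0; a1 <- 0.5 * e1
    s <- a0 + a1
    lp <- log(s)
    a0 <- a0 / s; a1 <- a1 / s
    if (n > 1L) for (t in 2:n) {
      b <- enum_bit(idx, t)
      e0 <- (1 - p_d) * (1 - b) + p_d * b
      e1 <- (1 - p_d) * b + p_d * (1 - b)
      t0 <- a0 * p_r + a1 * (1 - p_r)
      t1 <- a0 * (1 - p_r) + a1 * p_r
      a0 <- t0 * e0; a1 <- t1 * e1
      s <- a0 + a1
      lp <- lp + log(s)
      s[s == 0] <- 1
      a0 <- a0 / s; a1 <- a1 / s
    }
  }
  if (n <= 20L) .dmsdt_cache[[key]] <- lp
  lp
}

# Feature values for every sequence index 0..2^n-1, computed in one
# vectorized sweep. Cached per n. Returns a list of numeric vectors
# f1, f2_raw, f3, f4.
enum_features <- function(n) {
  n <- check_enum(n)
  key <- sprintf("feat_%d", n)
  if (!is.null(.dmsdt_cache[[key]])) return(.dmsdt_cache[[key]])
  idx <- 0:(2^n - 1L)
  prev <- enum_bit(idx, 1L)
  run <- rep(1, length(idx)); maxrun <- run
  alt <- rep(1, length(idx)); maxalt <- alt
  reps <- rep(0, length(idx))
  ones <- prev
  if (n > 1L) for (t in 2:n) {
    b <- enum_bit(idx, t)
    same <- as.numeric(b == prev)
    run <- run * same + 1
    maxrun <- pmax(maxrun, run)
    alt <- alt * (1 - same) + 1
    maxalt <- pmax(maxalt, alt)
    reps <- reps + same
    ones <- ones + b
    prev <- b
  }
  out <- list(f1 = maxrun, f2_raw = maxalt, f3 = reps,
              f4 = abs(2 * ones - n))
  if (n <= 20L) .dmsdt_cache[[key]] <- out
  out
}
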