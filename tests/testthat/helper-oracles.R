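# Independent oracles and fixture builders, deliberately kept apart from the
# package's own code paths.

# All 2^n sequences as a 0/1 matrix; row i+1 is the binary expansion of i
# with bit 1 (LSB) at position 1.
all_sequences <- function(n) {
  idx <- 0:(2^n - 1L)
  m <- vapply(seq_len(n),
              function(t) as.integer(bitwAnd(idx, bitwShiftL(1L, t - 1L)) != 0L),
              integer(length(idx)))
  matrix(m, nrow = length(idx), ncol = n)
}

# Exhaustive marginalization over the 2^n hidden Markov sequences:
# P(S | DMS) = sum_h P(h) p_d^hamming(S,h) (1-p_d)^(n-hamming(S,h)).
# Returns log-probabilities for every sequence index 0..2^n-1.
brute_log_dms <- function(n, p_r, p_d) {
  idx <- 0:(2^n - 1L)
  bits <- all_sequences(n)
  R <- if (n == 1L) rep(0, length(idx)) else
    rowSums(bits[, -1L, drop = FALSE] == bits[, -n, drop = FALSE])
  ph <- 0.5 * p_r^R * (1 - p_r)^(n - 1 - R)
  popc <- rowSums(bits)
  D <- outer(idx, idx, function(a, b) popc[bitwXor(a, b) + 1L])
  w <- p_d^(0:n) * (1 - p_d)^(n - (0:n))
  P <- matrix(w[D + 1L], nrow = length(idx))
  log(as.vector(P %*% ph))
}

# Brute-force longest monochromatic block: maximum over all contiguous
# windows that contain a single color.
brute_longest_run <- function(s) {
  n <- length(s)
  best <- 0L
  for (i in seq_len(n)) for (j in i:n)
    if (length(unique(s[i:j])) == 1L) best <- max(best, j - i + 1L)
  best
}

# Brute-force longest strictly alternating contiguous block.
brute_longest_alt <- function(s) {
  n <- length(s)
  best <- 1L
  for (i in seq_len(n)) for (j in i:n) {
    w <- s[i:j]
    if (length(w) < 2L || all(diff(w) != 0L)) best <- max(best, j - i + 1L)
  }
  best
}

random_sequences <- function(n_seq, n) {
  matrix(sample(0:1, n_seq * n, replace = TRUE), nrow = n_seq)
}

study_conditions <- list(LD = 0.1, MD = 0.2, HD = 0.3)
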