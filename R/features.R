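# The four candidate pattern features. Each is a function of the sequence
# returning an integer; all are invariant to complementing the colors and to
# reversing the sequence. F1, F3, F4 increase with pattern strength; raw F2
# (longest alternation) increases with randomness, so the stored feature is
# -F2, making "larger = more pattern-like" uniform across features.

#' Longest run (F1)
#'
#' Length, in tokens, of the longest contiguous block of a single color.
#'
#' @param x sequences (matrix, 0/1 vector, character strings, or session).
#' @return integer vector, one value per sequence, in \code{1..n}.
#' @examples
#' longest_run("11100000011111111000")
#' @export
longest_run <- function(x) {
  m <- as_token_matrix(x)
  apply(m, 1L, function(s) max(rle(s)$lengths))
}

#' Longest alternation (raw F2)
#'
#' Length, in tokens, of the longest contiguous strictly alternating block.
#' A single token counts as an alternating block of length 1. Large values
#' are evidence of randomness, so models use the negated value
#' (see \code{\link{feature_matrix}}).
#'
#' @inheritParams longest_run
#' @return integer vector in \code{1..n}.
#' @export
longest_alternation <- function(x) {
  m <- as_token_matrix(x)
  apply(m, 1L, function(s) {
    if (length(s) == 1L) return(1L)
    ch <- diff(s) != 0L            # TRUE where adjacent tokens differ
    r <- rle(ch)
    w <- r$lengths[r$values]
    if (length(w) == 0L) 1L else max(w) + 1L
  })
}

#' Number of repetitions (F3)
#'
#' Count of adjacent token pairs with equal colors. In a sequence of length
#' n, F3 plus the number of alternations is always n - 1, so F3 and the
#' alternation count carry identical information (perfect negative
#' correlation).
#'
#' @inheritParams longest_run
#' @return integer vector in \code{0..n-1}; requires n >= 2.
#' @export
n_repetitions <- function(x) {
  m <- as_token_matrix(x)
  if (ncol(m) < 2L)
    stop("repetition count needs sequences of length >= 2", call. = FALSE)
  rowSums(m[, -1L, drop = FALSE] == m[, -ncol(m), drop = FALSE])
}

#' Color predominance (F4)
#'
#' Absolute difference between the counts of the two colors,
#' \code{|count(blue) - count(yellow)|}. Has the parity of n.
#'
#' @inheritParams longest_run
#' @return integer vector in \code{0..n}.
#' @export
color_predominance <- function(x) {
  m <- as_token_matrix(x)
  abs(2L * rowSums(m) - ncol(m))
}

#' Feature matrix for a set of sequences
#'
#' Evaluates the requested features on each sequence. The longest-alternation
#' feature is stored sign-flipped (column \code{f2}, values \code{-n..-1}) so
#' that larger values of every stored feature indicate a more patterned
#' sequence.
#'
#' @inheritParams longest_run
#' @param subset integer feature ids, a non-empty subset of \code{1:4}.
#' @return numeric matrix, one row per sequence, columns named
#'   \code{f1}, \code{f2}, \code{f3}, \code{f4} as requested.
#' @examples
#' feature_matrix(c("11111111111111111111", "10101010101010101010"))
#' @export
feature_matrix <- function(x, subset = 1:4) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L || !all(subset %in% 1:4))
    stop("'subset' must be a non-empty subset of 1:4", call. = FALSE)
  m <- as_token_matrix(x)
  cols <- lapply(subset, function(k) switch(k,
    longest_run(m),
    -longest_alternation(m),
    n_repetitions(m),
    color_predominance(m)))
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("f", subset)
  out
}

# Internal: feature vector over the enumerated sequence space, with the F2
# sign flip applied, as used by feature observers and exact distributions.
enum_feature <- function(feature, n) {
  ef <- enum_features(n)
  switch(feature,
         f1 = ef$f1, f2 = -ef$f2_raw, f3 = ef$f3, f4 = ef$f4,
         stop("unknown feature id", call. = FALSE))
}
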