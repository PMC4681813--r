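as_seq_string <- function(seq) {
  if (inherits(seq, "symbol_sequence")) return(unclass(seq))
  if (is.character(seq) && length(seq) == 1L) return(seq)
  if (is.character(seq)) return(paste(seq, collapse = ""))
  stop("invalid input: expected a string or symbol_sequence", call. = FALSE)
}

#' Lempel-Ziv (1976) complexity
#'
#' Number of blocks in the LZ-76 exhaustive-history parsing of a symbol
#' sequence: scanning left to right, each block is the shortest continuation
#' not reproducible from the preceding history; the final block is counted
#' whether or not it is novel. For example
#' `"01001101010111001001"` parses as `0|1|00|11|0101|0111|0010|01`, eight
#' blocks.
#'
#' @param seq A character string (any finite alphabet), character vector of
#'   single symbols, or `symbol_sequence`.
#' @return Integer block count (`0` for the empty sequence).
#' @export
#' @examples
#' lz76_count("01001101010111001001")  # 8
lz76_count <- function(seq) {
  lz76_count_cpp(as_seq_string(seq))
}

#' Normalized Lempel-Ziv complexity
#'
#' `lz76_count(seq) * log_k(n) / n` for a length-`n` sequence over a
#' `k`-letter alphabet; approaches 1 for long i.i.d. equiprobable sequences
#' and 0 for eventually periodic ones.
#'
#' @param seq Sequence as in [lz76_count()].
#' @param k Alphabet size (default 4; must be >= 2).
#' @return Non-negative real.
#' @export
lz76_normalized <- function(seq, k = 4L) {
  if (k < 2) stop("domain error: alphabet size k must be >= 2", call. = FALSE)
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (n < 2L) stop("invalid input: need a sequence of length >= 2", call. = FALSE)
  lz76_count_cpp(s) * (log(n) / log(k)) / n
}

# counts of overlapping length-L substrings
block_counts <- function(s, L) {
  n <- nchar(s)
  table(substring(s, 1:(n - L + 1L), L:n))
}

#' Block entropy of a symbol sequence
#'
#' Plug-in Shannon entropy (bits) of the empirical distribution of
#' overlapping length-`L` substrings.
#'
#' @param seq Sequence as in [lz76_count()].
#' @param L Block length, `1 <= L <= nchar(seq)`.
#' @return Entropy in bits.
#' @export
block_entropy <- function(seq, L) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (L < 1L || L > n) {
    stop("invalid input: block length L must be between 1 and the sequence length",
         call. = FALSE)
  }
  p <- as.numeric(block_counts(s, L))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Effective measure complexity of a symbol sequence
#'
#' Estimates conditional entropies `h_L = H(L+1) - H(L)` (bits; `h_0 = H(1)`)
#' from plug-in block entropies, takes the last reliable `h_L` as the
#' entropy-rate estimate `h`, and returns
#' `EMC = sum_{L=0}^{L_max-1} (h_L - h)`: the cumulative excess of
#' conditional entropies over the entropy rate, a measure of sequence
#' structure rather than randomness (0 for a memoryless source).
#'
#' Block lengths are considered reliable while the number of distinct
#' observed blocks stays below `sqrt(n)`; a requested `L_max` beyond that is
#' truncated with a warning, and the profile flags undersampled lengths.
#'
#' @param seq Sequence as in [lz76_count()].
#' @param L_max Maximum history length, or `NULL` (default) to choose the
#'   largest reliable length automatically (capped at `cap`).
#' @param cap Upper bound on the automatic `L_max` (default 8).
#' @return List with `emc` (bits) and `profile`, a list holding the block
#'   entropies `H`, conditional entropies `h_L`, `entropy_rate`, `L_max`
#'   used, and an `undersampled` flag per length.
#' @export
emc <- function(seq, L_max = NULL, cap = 8L) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (n < 2L) stop("invalid input: sequence too short", call. = FALSE)
  distinct <- function(L) length(block_counts(s, L))
  reliable_max <- 1L
  while (reliable_max < min(n - 1L, 64L) &&
         distinct(reliable_max + 1L) < sqrt(n)) {
    reliable_max <- reliable_max + 1L
  }
  if (is.null(L_max)) {
    L_max <- min(reliable_max, cap)
  } else if (L_max > reliable_max) {
    warning(sprintf("sequence too short for L_max = %d; truncated to %d",
                    L_max, reliable_max), call. = FALSE)
    L_max <- reliable_max
  }
  L_max <- max(1L, as.integer(L_max))
  H <- vapply(seq_len(L_max), function(L) block_entropy(s, L), numeric(1))
  hL <- c(H[1], diff(H))                      # h_0 .. h_{L_max-1}
  h <- hL[length(hL)]
  undersampled <- vapply(seq_len(L_max), function(L) distinct(L) >= sqrt(n),
                         logical(1))
  list(emc = sum(hL - h),
       profile = list(H = H, h_L = hL, entropy_rate = h, L_max = L_max,
                      undersampled = undersampled))
}
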