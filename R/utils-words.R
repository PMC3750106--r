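# Label words are integers: bit a-1 encodes carbon atom a (atom 1 = least
# significant bit). The printed form is atom-1-leftmost, e.g. "01xx" fixes
# atom 1 unlabeled and atom 2 labeled.

#' Convert integer label words to printed strings
#'
#' @param w integer vector of label words.
#' @param k number of atoms (string length).
#' @return character vector, atom 1 leftmost.
#' @keywords internal
word_to_string <- function(w, k) {
  if (k == 0L) return(rep("", length(w)))
  out <- matrix("0", nrow = length(w), ncol = k)
  for (a in seq_len(k)) {
    out[, a] <- as.character(bitwAnd(bitwShiftR(w, a - 1L), 1L))
  }
  apply(out, 1L, paste0, collapse = "")
}

#' Parse a printed label word (no wildcards) to an integer
#' @keywords internal
string_to_word <- function(s) {
  vapply(s, function(si) {
    bits <- strsplit(si, "")[[1]]
    if (!all(bits %in% c("0", "1"))) {
      stop("label word '", si, "' may only contain 0/1", call. = FALSE)
    }
    sum(as.integer(bits) * 2^(seq_along(bits) - 1L))
  }, numeric(1), USE.NAMES = FALSE)
}

#' All label words matching a 0/1/x pattern
#'
#' @param pattern string such as "1xxxx" or "#1xxxx" (atom 1 leftmost).
#' @param k expected number of atoms; checked against the pattern length.
#' @return integer vector of matching words.
#' @keywords internal
words_matching <- function(pattern, k) {
  pattern <- sub("^#", "", pattern)
  bits <- strsplit(tolower(pattern), "")[[1]]
  if (length(bits) != k) {
    stop("pattern '", pattern, "' has length ", length(bits),
         " but the fragment has ", k, " atoms", call. = FALSE)
  }
  if (!all(bits %in% c("0", "1", "x"))) {
    stop("pattern '", pattern, "' may only contain 0/1/x", call. = FALSE)
  }
  w <- 0:(2^k - 1L)
  keep <- rep(TRUE, length(w))
  for (a in seq_len(k)) {
    if (bits[a] != "x") {
      keep <- keep & (bitwAnd(bitwShiftR(w, a - 1L), 1L) == as.integer(bits[a]))
    }
  }
  w[keep]
}

#' Extract the subword carried by a set of atom positions
#'
#' Bit j-1 of the result is the bit of `w` at atom `positions[j]`, so the
#' result is itself a label word over the extracted atoms in the given order.
#'
#' @param w integer vector of words.
#' @param positions integer vector of 1-based atom positions.
#' @keywords internal
extract_subword <- function(w, positions) {
  out <- integer(length(w))
  for (j in seq_along(positions)) {
    out <- out + bitwAnd(bitwShiftR(w, positions[j] - 1L), 1L) * 2^(j - 1L)
  }
  out
}

#' Number of labeled atoms in each word
#' @keywords internal
word_weight <- function(w, k) {
  out <- integer(length(w))
  for (a in seq_len(k)) out <- out + bitwAnd(bitwShiftR(w, a - 1L), 1L)
  out
}
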