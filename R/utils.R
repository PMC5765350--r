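DNA_BASES <- c("A", "C", "G", "T")

# byte-value lookup: A/C/G/T -> 1..4 (case-insensitive), N -> NA,
# anything else -> -1 (caught as an invalid-alphabet error by callers)
.base_lookup <- local({
  lut <- rep(-1L, 256L)
  for (ch in c("A", "a")) lut[utf8ToInt(ch)] <- 1L
  for (ch in c("C", "c")) lut[utf8ToInt(ch)] <- 2L
  for (ch in c("G", "g")) lut[utf8ToInt(ch)] <- 3L
  for (ch in c("T", "t")) lut[utf8ToInt(ch)] <- 4L
  for (ch in c("N", "n")) lut[utf8ToInt(ch)] <- NA_integer_
  lut
})

#' Encode a nucleotide string as integer base codes
#'
#' A, C, G, T map to 1..4; N maps to NA. Any other character is an error.
#'
#' @param seq single nucleotide string (ACGTN, case-insensitive)
#' @return integer vector of base codes, one per character
#' @keywords internal
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  codes <- .base_lookup[as.integer(charToRaw(seq))]
  bad <- which(!is.na(codes) & codes < 0L)
  if (length(bad) > 0L) {
    stop("invalid character in sequence at position ", bad[1],
         " (alphabet is ACGTN)")
  }
  codes
}

# encode a set of equal-length strings into an n x l integer matrix
encode_seq_matrix <- function(seqs) {
  l <- unique(nchar(seqs))
  stopifnot(length(l) == 1L)
  big <- paste(seqs, collapse = "")
  codes <- .base_lookup[as.integer(charToRaw(big))]
  bad <- which(!is.na(codes) & codes < 0L)
  if (length(bad) > 0L) stop("invalid character in sequence (alphabet is ACGTN)")
  matrix(codes, nrow = length(seqs), ncol = l, byrow = TRUE)
}

#' Reverse-complement nucleotide strings
#' @param seq character vector of ACGTN strings
#' @return character vector of reverse complements
#' @keywords internal
revcomp_seq <- function(seq) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded operations do not disturb
#' the caller's RNG stream. A NULL seed leaves the stream alone.
#'
#' @param seed integer seed or NULL
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a distinct 31-bit sub-seed from a master seed and a stream index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}
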