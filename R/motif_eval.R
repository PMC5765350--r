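#' Area under the ROC curve by exact rank statistics
#'
#' Mann-Whitney formulation with midrank tie handling:
#' (#\{p > n\} + 0.5 #\{p = n\}) / (|pos| |neg|). All-tied inputs give
#' exactly 0.5; the value is invariant under any strictly monotone transform
#' of the pooled scores.
#'
#' @param pos,neg numeric score vectors for the two classes
#' @return AUROC in [0, 1]
#' @export
auroc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("undefined AUROC: empty score list")
  }
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Evaluate a motif on a peak set against a dinucleotide-shuffled null
#'
#' Positives are the maximum PWM log-odds scores of the top-N summit-window
#' sequences; negatives are the same statistic on one dinucleotide shuffle
#' of each window (1:1 pairing). Windows shorter than the motif width are
#' dropped from both classes symmetrically.
#'
#' @param x a \code{\link{pwm}}
#' @param ps a \code{\link{peak_set}}
#' @param genome named \code{DNAStringSet} or named character vector
#' @param seed integer seed controlling the shuffles
#' @param n top-N cut (default 500)
#' @param flank window half-width (default 250)
#' @param background,pseudocount log-odds scoring parameters
#' @param both_strands scan both strands (default TRUE)
#' @param shuffled_seqs optional precomputed negative sequences (one per
#'   window, same order), e.g. to share one null set across motifs
#' @return AUROC in [0, 1]
#' @export
evaluate_motif <- function(x, ps, genome, seed = NULL, n = 500L, flank = 250L,
                           background = rep(0.25, 4), pseudocount = 0.01,
                           both_strands = TRUE, shuffled_seqs = NULL) {
  stopifnot(inherits(x, "pwm"))
  top <- top_n_peaks(ps, n)
  seqs <- extract_window_sequences(top, genome, flank = flank)
  w <- pwm_width(x)
  keep <- nchar(seqs) >= w
  if (!any(keep)) stop("evaluation impossible: all windows shorter than motif")
  seqs <- seqs[keep]
  if (is.null(shuffled_seqs)) {
    shuffled_seqs <- shuffle_windows(seqs, seed = seed)
  } else {
    stopifnot(length(shuffled_seqs) >= length(keep))
    shuffled_seqs <- shuffled_seqs[keep]
  }
  sm <- to_score_matrix(x, background = background, pseudocount = pseudocount)
  pos <- .score_seqs(seqs, sm, both_strands)
  neg <- .score_seqs(shuffled_seqs, sm, both_strands)
  auroc(pos, neg)
}

# max_pwm_score over possibly unequal-length sequences, vectorized per
# length group
.score_seqs <- function(seqs, sm, both_strands = TRUE) {
  out <- numeric(length(seqs))
  for (l in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == l)
    cm <- encode_seq_matrix(seqs[idx])
    out[idx] <- .max_scores_matrix(cm, sm, both_strands)
  }
  out
}

#' Dinucleotide-shuffle a list of window sequences
#'
#' One shuffle per sequence, each drawn from an independent substream of the
#' given seed, so the same (sequence list, seed) pair always yields the same
#' null set.
#'
#' @param seqs character vector of sequences
#' @param seed integer seed or NULL
#' @return character vector of shuffled sequences
#' @export
shuffle_windows <- function(seqs, seed = NULL) {
  if (is.null(seed)) {
    return(vapply(seqs, dinucleotide_shuffle, character(1), USE.NAMES = FALSE))
  }
  vapply(seq_along(seqs), function(i) {
    dinucleotide_shuffle(seqs[i], seed = derive_seed(seed, i))
  }, character(1))
}

#' AUROC grid of motifs against peak sets
#'
#' Evaluates every motif on every peak set. Within one peak set all motifs
#' are scored against the same shuffled null sequences (seed-derived per
#' column) so they are compared on identical negatives. NULL peak-set
#' entries, or evaluations that fail, are recorded as missing with a
#' warning.
#'
#' @param motifs list of \code{\link{pwm}} objects
#' @param peaksets named list of \code{\link{peak_set}} objects (names
#'   become the grid columns; NULL entries give missing columns)
#' @param genome named \code{DNAStringSet} or named character vector
#' @param seed integer master seed
#' @param ... passed to \code{\link{evaluate_motif}}
#' @param n top-N cut (default 500)
#' @param flank window half-width (default 250)
#' @return numeric matrix, rows = motif names, columns = peak-set labels,
#'   class \code{auroc_grid}
#' @export
evaluate_grid <- function(motifs, peaksets, genome, seed = 1L, n = 500L,
                          flank = 250L, ...) {
  motif_names <- vapply(motifs, function(m) m$name, character(1))
  grid <- matrix(NA_real_, nrow = length(motifs), ncol = length(peaksets),
                 dimnames = list(motif_names, names(peaksets)))
  for (j in seq_along(peaksets)) {
    ps <- peaksets[[j]]
    if (is.null(ps)) next
    top <- top_n_peaks(ps, n)
    seqs <- extract_window_sequences(top, genome, flank = flank)
    nulls <- shuffle_windows(seqs, seed = derive_seed(seed, j))
    for (i in seq_along(motifs)) {
      grid[i, j] <- tryCatch(
        evaluate_motif(motifs[[i]], ps, genome, n = n, flank = flank,
                       shuffled_seqs = nulls, ...),
        error = function(e) {
          warning("motif '", motif_names[i], "' on '", names(peaksets)[j],
                  "': ", conditionMessage(e))
          NA_real_
        })
    }
  }
  class(grid) <- c("auroc_grid", class(grid))
  grid
}
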