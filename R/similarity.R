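#' Affinity-correlation similarity of two motifs
#'
#' Generates a shared background of \code{n} random uniform sequences of
#' length \code{l}, scores every sequence with the summed-probability
#' affinity of each motif (both strands), and returns the Pearson
#' correlation of the two affinity vectors. Because both strands are
#' scanned, a motif and its reverse complement produce identical affinity
#' vectors and hence similarity 1.
#'
#' @param a,b \code{\link{pwm}} objects
#' @param n number of background sequences (default 100000)
#' @param l background sequence length (default 100)
#' @param seed integer seed for the shared background
#' @param log_affinity correlate log(1 + affinity) instead of the raw
#'   affinity (heavy-tail damping; default FALSE)
#' @return Pearson r in [-1, 1], or NA when either affinity vector is
#'   constant
#' @export
similarity <- function(a, b, n = 100000L, l = 100L, seed = 1L,
                       log_affinity = FALSE) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  if (l < pwm_width(a) || l < pwm_width(b)) {
    stop("background too short: l = ", l, " < motif width")
  }
  seqs <- random_sequences(n, l, seed = seed)
  cm <- encode_seq_matrix(seqs)
  va <- .affinity_matrix(cm, a$matrix)
  vb <- .affinity_matrix(cm, b$matrix)
  .affinity_cor(va, vb, log_affinity)
}

.affinity_cor <- function(va, vb, log_affinity = FALSE) {
  if (log_affinity) {
    va <- log1p(va)
    vb <- log1p(vb)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Pairwise similarity matrix over a motif list
#'
#' All motifs are scored on one shared seeded background so every pair is
#' comparable; each affinity vector is computed once and each pair's
#' correlation once, making the matrix symmetric by construction with unit
#' diagonal (NA where an affinity vector is constant).
#'
#' @param motifs list of \code{\link{pwm}} objects
#' @inheritParams similarity
#' @return symmetric numeric matrix with motif names as dimnames and a
#'   \code{background_spec} attribute recording (n, l, seed)
#' @export
similarity_matrix <- function(motifs, n = 100000L, l = 100L, seed = 1L,
                              log_affinity = FALSE) {
  widths <- vapply(motifs, pwm_width, integer(1))
  if (any(widths > l)) stop("background too short for widest motif")
  nms <- vapply(motifs, function(m) m$name, character(1))
  seqs <- random_sequences(n, l, seed = seed)
  cm <- encode_seq_matrix(seqs)
  vecs <- lapply(motifs, function(m) .affinity_matrix(cm, m$matrix))
  k <- length(motifs)
  out <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    out[i, i] <- if (stats::sd(vecs[[i]]) == 0) NA_real_ else 1
    if (i < k) for (j in (i + 1L):k) {
      r <- .affinity_cor(vecs[[i]], vecs[[j]], log_affinity)
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  attr(out, "background_spec") <- list(n = as.integer(n), l = as.integer(l),
                                       seed = as.integer(seed))
  class(out) <- c("similarity_matrix", class(out))
  out
}

#' Interpret a similarity score
#'
#' r > 0.5 is the level typically seen between experiments on the same
#' transcription factor; 0.2 < r <= 0.5 indicates related motifs; anything
#' lower is dissimilar.
#'
#' @param r similarity value(s)
#' @return character vector in \{same_tf_level, related, dissimilar\}
#' @export
classify_similarity <- function(r) {
  stopifnot(all(!is.na(r)))
  ifelse(r > 0.5, "same_tf_level",
         ifelse(r > 0.2, "related", "dissimilar"))
}

#' Write a similarity matrix as TSV with its background spec
#' @param m a \code{similarity_matrix}
#' @param path output file
#' @export
write_similarity_matrix <- function(m, path) {
  spec <- attr(m, "background_spec")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(spec)) {
    writeLines(sprintf("#n=%d l=%d seed=%d", spec$n, spec$l, spec$seed), con)
  }
  writeLines(paste(c("motif", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    vals <- ifelse(is.na(m[i, ]), "", format(m[i, ], digits = 6))
    writeLines(paste(c(rownames(m)[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}
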