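#' Motif metadata
#'
#' Provenance record attached to every PWM: the protein it belongs to, the
#' dataset it was derived from, the derivation method, and whether the motif
#' is supported by the C2H2 recognition code (a property of recognition-code-
#' assisted discovery). Motifs produced by the recognition-code-assisted
#' method are by definition code-supported.
#'
#' @param protein protein identifier
#' @param source dataset label, e.g. \code{"hughes"}, \code{"trono_original"},
#'   \code{"trono_reprocessed"} or \code{"external:<label>"}
#' @param method one of \code{"rcade"}, \code{"meme"}, \code{"external"}
#' @param recognition_code_supported logical; forced TRUE when
#'   \code{method == "rcade"}
#' @param trained_on_non_ere_peaks logical or NA
#' @param is_in_vitro logical; TRUE for motifs from in vitro assays
#' @return a \code{motif_metadata} list
#' @export
motif_metadata <- function(protein = "unknown", source = "unknown",
                           method = c("external", "rcade", "meme"),
                           recognition_code_supported = FALSE,
                           trained_on_non_ere_peaks = NA,
                           is_in_vitro = FALSE) {
  method <- match.arg(method)
  if (method == "rcade") recognition_code_supported <- TRUE
  structure(list(protein = protein, source = source, method = method,
                 recognition_code_supported = isTRUE(recognition_code_supported),
                 trained_on_non_ere_peaks = trained_on_non_ere_peaks,
                 is_in_vitro = isTRUE(is_in_vitro)),
            class = "motif_metadata")
}

#' Position weight matrix
#'
#' A PWM is a width x 4 matrix of base probabilities (columns A, C, G, T;
#' each row a probability distribution) with a name and provenance metadata.
#' Rows off unity by at most \code{tol} are renormalized; larger deviations
#' are an error.
#'
#' @param name motif identifier
#' @param matrix numeric width x 4 matrix, rows summing to 1
#' @param metadata a \code{\link{motif_metadata}} object
#' @param tol row-sum tolerance before renormalization fails (default 1e-3)
#' @return a \code{pwm} object
#' @export
pwm <- function(name, matrix, metadata = motif_metadata(), tol = 1e-3) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (ncol(m) != 4L) stop("PWM matrix must have 4 columns (A,C,G,T)")
  if (nrow(m) < 1L) stop("PWM must have width >= 1")
  if (any(m < -1e-12) || any(m > 1 + tol)) {
    stop("malformed motif '", name, "': probabilities outside [0,1]")
  }
  m[m < 0] <- 0
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0L) {
    stop("malformed motif '", name, "': row ", off[1],
         " sums to ", format(rs[off[1]]), " (must be 1 within ", tol, ")")
  }
  m <- m / rs
  dimnames(m) <- list(NULL, DNA_BASES)
  structure(list(name = name, matrix = m, metadata = metadata), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "' width ", nrow(x$matrix),
      " (", x$metadata$method, ", ", x$metadata$source, ")\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

pwm_width <- function(x) nrow(x$matrix)

#' Reverse-complement a PWM
#'
#' Rows are reversed and within each row A swaps with T and C with G.
#' Applying the operation twice returns the original matrix exactly;
#' metadata is preserved.
#'
#' @param x a \code{pwm}
#' @return the reverse-complement \code{pwm}
#' @export
reverse_complement <- function(x) {
  stopifnot(inherits(x, "pwm"))
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), rev(seq_len(4L)), drop = FALSE]
  dimnames(m) <- list(NULL, DNA_BASES)
  out <- x
  out$matrix <- m
  out
}

#' Log-odds score matrix from a PWM
#'
#' Entry (i, b) is \code{log2((p[i,b] + pseudocount * bg[b]) /
#' ((1 + pseudocount) * bg[b]))}. A uniform PWM under a uniform background
#' gives the all-zero matrix regardless of pseudocount.
#'
#' @param x a \code{pwm}
#' @param background length-4 base probability vector (A,C,G,T), all > 0
#' @param pseudocount nonnegative smoothing weight (default 0.01)
#' @return width x 4 numeric matrix of base-2 log odds, class
#'   \code{score_matrix}
#' @export
to_score_matrix <- function(x, background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(inherits(x, "pwm"))
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 probabilities summing to 1")
  }
  if (any(background <= 0)) stop("invalid background: entries must be > 0")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  bg <- matrix(background, nrow = nrow(x$matrix), ncol = 4L, byrow = TRUE)
  sm <- log2((x$matrix + pseudocount * bg) / ((1 + pseudocount) * bg))
  dimnames(sm) <- list(NULL, DNA_BASES)
  class(sm) <- c("score_matrix", class(sm))
  sm
}

# reverse-complement a plain score (or probability) matrix
.revcomp_matrix <- function(m) {
  out <- m[rev(seq_len(nrow(m))), rev(seq_len(4L)), drop = FALSE]
  dimnames(out) <- list(NULL, DNA_BASES)
  out
}

# per-offset sums of score-matrix entries along codes; NA codes (N) add 0
.scan_logodds <- function(codes, sm) {
  w <- nrow(sm)
  k <- length(codes) - w + 1L
  total <- numeric(k)
  idx <- seq_len(k)
  for (j in seq_len(w)) {
    contrib <- sm[j, ][codes[idx + j - 1L]]
    contrib[is.na(contrib)] <- 0
    total <- total + contrib
  }
  total
}

#' Maximum PWM match score of a sequence
#'
#' Slides the log-odds matrix over every offset of the sequence (and of its
#' reverse complement when \code{both_strands}) and returns the single best
#' window sum. Positions with N contribute 0 (background-equivalent).
#'
#' @param seq nucleotide string (ACGTN)
#' @param sm score matrix from \code{\link{to_score_matrix}}
#' @param both_strands scan the reverse strand too (default TRUE; ChIP peaks
#'   are strandless)
#' @return the maximum window score
#' @export
max_pwm_score <- function(seq, sm, both_strands = TRUE) {
  codes <- encode_seq(seq)
  w <- nrow(sm)
  if (length(codes) < w) {
    stop("sequence too short: length ", length(codes), " < motif width ", w)
  }
  best <- max(.scan_logodds(codes, sm))
  if (both_strands) {
    best <- max(best, .scan_logodds(codes, .revcomp_matrix(sm)))
  }
  best
}

# vectorized max scores over many equal-length sequences (code matrix rows)
.max_scores_matrix <- function(code_mat, sm, both_strands = TRUE) {
  w <- nrow(sm)
  l <- ncol(code_mat)
  stopifnot(l >= w)
  k <- l - w + 1L
  scan1 <- function(mat) {
    best <- rep(-Inf, nrow(code_mat))
    for (off in seq_len(k)) {
      total <- numeric(nrow(code_mat))
      for (j in seq_len(w)) {
        contrib <- mat[j, ][code_mat[, off + j - 1L]]
        contrib[is.na(contrib)] <- 0
        total <- total + contrib
      }
      best <- pmax(best, total)
    }
    best
  }
  best <- scan1(sm)
  if (both_strands) best <- pmax(best, scan1(.revcomp_matrix(sm)))
  best
}

#' Summed-affinity score of a sequence under a PWM
#'
#' Sums, over all offsets (and both strands when requested), the product over
#' motif positions of the probability of the observed base — a Boltzmann-like
#' predicted affinity. N counts as probability 0.25 (neutral under a uniform
#' background).
#'
#' @param seq nucleotide string (ACGTN)
#' @param x a \code{pwm}
#' @param both_strands include reverse-strand windows (default TRUE)
#' @return nonnegative affinity
#' @export
affinity_score <- function(seq, x, both_strands = TRUE) {
  stopifnot(inherits(x, "pwm"))
  codes <- encode_seq(seq)
  w <- pwm_width(x)
  if (length(codes) < w) {
    stop("sequence too short: length ", length(codes), " < motif width ", w)
  }
  sum(.scan_affinity(codes, x$matrix)) +
    if (both_strands) sum(.scan_affinity(codes, .revcomp_matrix(x$matrix))) else 0
}

.scan_affinity <- function(codes, pm) {
  w <- nrow(pm)
  k <- length(codes) - w + 1L
  total <- rep(1, k)
  idx <- seq_len(k)
  for (j in seq_len(w)) {
    contrib <- pm[j, ][codes[idx + j - 1L]]
    contrib[is.na(contrib)] <- 0.25
    total <- total * contrib
  }
  total
}

# vectorized affinities over many equal-length sequences
.affinity_matrix <- function(code_mat, pm, both_strands = TRUE) {
  w <- nrow(pm)
  l <- ncol(code_mat)
  stopifnot(l >= w)
  k <- l - w + 1L
  n <- nrow(code_mat)
  scan1 <- function(mat) {
    acc <- numeric(n)
    for (off in seq_len(k)) {
      prod <- rep(1, n)
      for (j in seq_len(w)) {
        contrib <- mat[j, ][code_mat[, off + j - 1L]]
        contrib[is.na(contrib)] <- 0.25
        prod <- prod * contrib
      }
      acc <- acc + prod
    }
    acc
  }
  acc <- scan1(pm)
  if (both_strands) acc <- acc + scan1(.revcomp_matrix(pm))
  acc
}
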