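#' Repeat-class annotation
#'
#' Genomic intervals labelled with an ERE/transposon class name. The class
#' list is the ordered set of distinct names as first encountered.
#'
#' @param intervals data.frame with columns chrom, start, end, class
#'   (0-based half-open coordinates)
#' @return a \code{repeat_annotation} object
#' @export
repeat_annotation <- function(intervals) {
  req <- c("chrom", "start", "end", "class")
  if (!all(req %in% names(intervals))) {
    stop("repeat table must have columns: ", paste(req, collapse = ", "))
  }
  intervals <- as.data.frame(intervals)[req]
  if (nrow(intervals) > 0L) {
    bad <- which(intervals$end <= intervals$start)
    if (length(bad) > 0L) {
      stop("malformed repeat interval at row ", bad[1], ": end <= start")
    }
  }
  structure(list(intervals = intervals,
                 classes = unique(as.character(intervals$class))),
            class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat("RepeatAnnotation: ", nrow(x$intervals), " intervals, ",
      length(x$classes), " classes\n", sep = "")
  invisible(x)
}

.repeats_granges <- function(repeats) {
  df <- repeats$intervals
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read a repeat annotation
#'
#' \code{bed_class} is a 4-column TSV (chrom, start, end, class; 0-based
#' half-open). \code{repeatmasker_out} is the whitespace-separated
#' RepeatMasker table whose columns 5-7 give the genomic position (1-based
#' inclusive) and column 10 the repeat name, used here as the class; header
#' lines (non-numeric first field) are skipped.
#'
#' @param text annotation content (single string or vector of lines)
#' @param format \code{"bed_class"} or \code{"repeatmasker_out"}
#' @return a \code{\link{repeat_annotation}}
#' @export
read_repeats <- function(text, format = c("bed_class", "repeatmasker_out")) {
  format <- match.arg(format)
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0))
  if (length(lines) == 0L) return(repeat_annotation(empty))
  rows <- list()
  for (i in seq_along(lines)) {
    if (format == "bed_class") {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 4L) stop("line ", i, ": expected 4 tab-separated fields")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end)) stop("line ", i, ": non-integer coordinate")
      if (end <= start) stop("malformed repeat interval at line ", i)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = f[1], start = start, end = end, class = f[4])
    } else {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (suppressWarnings(is.na(as.numeric(f[1])))) next  # header line
      if (length(f) < 10L) stop("line ", i, ": truncated RepeatMasker row")
      start <- suppressWarnings(as.integer(f[6]))
      end <- suppressWarnings(as.integer(f[7]))
      if (is.na(start) || is.na(end)) stop("line ", i, ": non-integer coordinate")
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = f[5], start = start - 1L, end = end, class = f[10])
    }
  }
  if (length(rows) == 0L) return(repeat_annotation(empty))
  repeat_annotation(do.call(rbind, rows))
}

#' Read a repeat annotation from a file
#' @param path file path
#' @inheritParams read_repeats
#' @export
read_repeats_file <- function(path, format = c("bed_class", "repeatmasker_out")) {
  read_repeats(readLines(path, warn = FALSE), format = format)
}

#' Write a repeat annotation as BED+class text
#' @param repeats a \code{\link{repeat_annotation}}
#' @param path optional output file
#' @export
write_repeats <- function(repeats, path = NULL) {
  df <- repeats$intervals
  text <- paste(df$chrom, df$start, df$end, df$class, sep = "\t")
  text <- paste(text, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' ERE enrichment profile of a peak set
#'
#' For every repeat class, the fraction of the top-N peaks whose summit
#' window intersects at least one interval of that class. A peak whose
#' window spans intervals of several classes contributes to each, so the
#' fractions may sum to more than 1.
#'
#' @param ps a \code{\link{peak_set}}
#' @param repeats a \code{\link{repeat_annotation}}
#' @param n top-N cut (default 500)
#' @param flank window half-width (default 250)
#' @return an \code{ere_profile}: protein, dataset, named fraction vector
#'   over the annotation's classes
#' @export
compute_profile <- function(ps, repeats, n = 500L, flank = 250L) {
  top <- top_n_peaks(ps, n)$peaks
  if (nrow(top) == 0L) stop("undefined profile: empty peak set")
  fractions <- stats::setNames(numeric(length(repeats$classes)),
                               repeats$classes)
  if (nrow(repeats$intervals) > 0L) {
    gw <- .window_granges(top, flank)
    gr <- .repeats_granges(repeats)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gw, gr))
    cls <- repeats$intervals$class[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    for (cl in unique(cls)) {
      fractions[[cl]] <- length(unique(qh[cls == cl])) / nrow(top)
    }
  }
  structure(list(protein = ps$protein, dataset = ps$dataset,
                 fractions = fractions),
            class = "ere_profile")
}

#' Pearson correlation between two ERE profiles
#'
#' Profiles must share the same class ordering. A constant (zero-variance)
#' fraction vector makes the correlation undefined; NA is returned rather
#' than an arbitrary number.
#'
#' @param p,q \code{ere_profile} objects
#' @return Pearson r in [-1, 1], or NA when undefined
#' @export
profile_correlation <- function(p, q) {
  stopifnot(inherits(p, "ere_profile"), inherits(q, "ere_profile"))
  if (!identical(names(p$fractions), names(q$fractions))) {
    stop("profiles have different class orderings")
  }
  x <- p$fractions
  y <- q$fractions
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Matched versus unmatched ERE-profile agreement
#'
#' Given one profile per protein from each of two datasets (k shared
#' proteins), pools all 2k profiles and computes every pairwise Pearson
#' correlation. The k same-protein cross-dataset pairs are the matched
#' comparisons; the remaining C(2k, 2) - k pairs (including within-dataset
#' different-protein pairs) are the unmatched comparisons. The summary
#' reports the fraction of each group strictly above a threshold, either
#' fixed or chosen to maximize the matched-minus-unmatched separation (ties
#' resolved to the lowest threshold).
#'
#' @param profiles_a,profiles_b lists of \code{ere_profile} objects covering
#'   the same proteins
#' @param threshold_rule \code{"best_separation"} or \code{"fixed"}
#' @param threshold numeric threshold, required for \code{"fixed"}
#' @return an \code{agreement_summary} with matched/unmatched correlation
#'   lists, the threshold, and the two above-threshold fractions
#' @export
matched_vs_unmatched <- function(profiles_a, profiles_b,
                                 threshold_rule = c("best_separation", "fixed"),
                                 threshold = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  k <- length(profiles_a)
  if (k < 2L || length(profiles_b) != k) {
    stop("insufficient proteins: need the same >= 2 proteins in both lists")
  }
  pa <- vapply(profiles_a, function(p) p$protein, character(1))
  pb <- vapply(profiles_b, function(p) p$protein, character(1))
  if (!setequal(pa, pb) || anyDuplicated(pa) || anyDuplicated(pb)) {
    stop("profile lists must cover the same distinct proteins")
  }
  profiles_b <- profiles_b[match(pa, pb)]
  pooled <- c(profiles_a, profiles_b)
  mat <- vapply(pooled, function(p) p$fractions,
                numeric(length(pooled[[1]]$fractions)))
  suppressWarnings(cm <- stats::cor(mat))
  cm[!is.finite(cm)] <- NA_real_
  idx_m <- cbind(seq_len(k), k + seq_len(k))
  matched <- cm[idx_m]
  all_pairs <- which(upper.tri(cm), arr.ind = TRUE)
  is_matched <- (all_pairs[, 2] - all_pairs[, 1] == k) & (all_pairs[, 1] <= k)
  unmatched <- cm[all_pairs[!is_matched, , drop = FALSE]]
  frac_above <- function(v, t) mean(v[!is.na(v)] > t)
  if (threshold_rule == "fixed") {
    if (is.null(threshold)) stop("fixed threshold rule requires `threshold`")
    t_star <- threshold
  } else {
    cand <- sort(unique(c(matched, unmatched)))
    cand <- cand[!is.na(cand)]
    sep <- vapply(cand, function(t) {
      frac_above(matched, t) - frac_above(unmatched, t)
    }, numeric(1))
    t_star <- cand[which.max(sep)]  # which.max returns the first (lowest)
  }
  structure(list(matched_correlations = matched,
                 unmatched_correlations = unmatched,
                 threshold = t_star,
                 frac_matched_above = frac_above(matched, t_star),
                 frac_unmatched_above = frac_above(unmatched, t_star)),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("Agreement: ", length(x$matched_correlations), " matched / ",
      length(x$unmatched_correlations), " unmatched comparisons\n",
      "threshold r = ", format(x$threshold, digits = 3),
      "; matched above: ", format(100 * x$frac_matched_above, digits = 3),
      "%; unmatched above: ", format(100 * x$frac_unmatched_above, digits = 3),
      "%\n", sep = "")
  invisible(x)
}
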