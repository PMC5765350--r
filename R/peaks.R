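#' Construct a peak set
#'
#' A peak set ties a protein and dataset label to a table of scored genomic
#' intervals with summits. Coordinates are 0-based half-open (BED
#' convention); summits are absolute 0-based positions inside the interval.
#'
#' @param protein protein identifier
#' @param dataset dataset label (e.g. \code{"hughes"}, \code{"trono_original"})
#' @param peaks data.frame with columns chrom, start, end, name, score,
#'   summit
#' @return a \code{peak_set} object
#' @export
peak_set <- function(protein, dataset, peaks) {
  req <- c("chrom", "start", "end", "name", "score", "summit")
  if (!all(req %in% names(peaks))) {
    stop("peaks table must have columns: ", paste(req, collapse = ", "))
  }
  peaks <- as.data.frame(peaks)[req]
  if (nrow(peaks) > 0L) {
    bad <- which(peaks$end <= peaks$start)
    if (length(bad) > 0L) {
      stop("malformed interval at row ", bad[1], ": end <= start")
    }
    bad <- which(peaks$summit < peaks$start | peaks$summit >= peaks$end)
    if (length(bad) > 0L) {
      stop("malformed summit at row ", bad[1], ": outside [start, end)")
    }
  }
  structure(list(protein = protein, dataset = dataset, peaks = peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("PeakSet ", x$protein, " / ", x$dataset, ": ", nrow(x$peaks),
      " peaks\n", sep = "")
  invisible(x)
}

n_peaks <- function(ps) nrow(ps$peaks)

#' Read a peak set from BED-like text
#'
#' Expects tab-separated columns chrom, start, end, name, score,
#' summit-offset, where the summit offset is relative to start and the
#' sentinel -1 means "use the interval midpoint".
#'
#' @param text peak file content (single string or vector of lines)
#' @param protein,dataset labels attached to the resulting set
#' @return a \code{\link{peak_set}}
#' @export
read_peaks <- function(text, protein = "unknown", dataset = "unknown") {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(peak_set(protein, dataset,
                    data.frame(chrom = character(0), start = integer(0),
                               end = integer(0), name = character(0),
                               score = numeric(0), summit = integer(0))))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("line ", i, ": expected 6 tab-separated fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    offset <- suppressWarnings(as.integer(f[6]))
    score <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end) || is.na(offset)) {
      stop("line ", i, ": non-integer coordinate")
    }
    if (is.na(score)) stop("line ", i, ": non-numeric score")
    if (end <= start) stop("malformed interval at line ", i, ": end <= start")
    summit <- if (offset == -1L) start + (end - start) %/% 2L else start + offset
    if (summit < start || summit >= end) {
      stop("line ", i, ": summit outside [start, end)")
    }
    data.frame(chrom = f[1], start = start, end = end, name = f[4],
               score = score, summit = summit)
  })
  peak_set(protein, dataset, do.call(rbind, rows))
}

#' Read a peak set from a file
#' @param path file path
#' @inheritParams read_peaks
#' @export
read_peaks_file <- function(path, protein = "unknown", dataset = "unknown") {
  read_peaks(readLines(path, warn = FALSE), protein = protein,
             dataset = dataset)
}

#' Write a peak set as BED-like text
#' @param ps a \code{\link{peak_set}}
#' @param path optional output file
#' @return the text, invisibly when \code{path} is given
#' @export
write_peaks <- function(ps, path = NULL) {
  p <- ps$peaks
  text <- paste(p$chrom, p$start, p$end, p$name,
                format(p$score, trim = TRUE), p$summit - p$start,
                sep = "\t")
  text <- paste(text, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

.peaks_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Merge nearby peaks
#'
#' Peaks that overlap or lie within \code{max_gap} bases of each other on the
#' same chromosome are unioned into a single peak. The merged peak takes the
#' maximum member score and the summit of the highest-scoring member (score
#' ties broken by leftmost start). Idempotent under re-merging.
#'
#' @param ps a \code{\link{peak_set}}
#' @param max_gap maximum allowed gap in bases (default 50)
#' @return merged \code{\link{peak_set}}
#' @export
merge_peaks <- function(ps, max_gap = 50L) {
  p <- ps$peaks
  if (nrow(p) <= 1L) return(ps)
  gr <- .peaks_granges(p)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  # representative member per merged peak: highest score, ties by start
  ord <- order(grp, -p$score, p$start)
  rep_idx <- ord[!duplicated(grp[ord])]
  rep_grp <- grp[rep_idx]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged))[rep_grp],
    start = GenomicRanges::start(merged)[rep_grp] - 1L,
    end = GenomicRanges::end(merged)[rep_grp],
    name = p$name[rep_idx],
    score = p$score[rep_idx],
    summit = p$summit[rep_idx])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  peak_set(ps$protein, ps$dataset, out)
}

#' Select the top-N peaks by enrichment score
#'
#' Returns the min(n, available) highest-scoring peaks; score ties at the
#' rank boundary are broken by (chrom, start) ascending so the selection is
#' deterministic.
#'
#' @param ps a \code{\link{peak_set}}
#' @param n number of peaks to keep (default 500)
#' @return a \code{\link{peak_set}} with at most \code{n} peaks
#' @export
top_n_peaks <- function(ps, n = 500L) {
  stopifnot(n >= 1L)
  p <- ps$peaks
  ord <- order(-p$score, p$chrom, p$start)
  keep <- ord[seq_len(min(n, nrow(p)))]
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  peak_set(ps$protein, ps$dataset, out)
}

#' Summit-centred window
#'
#' The interval [summit - flank, summit + flank + 1) clipped to
#' [0, chrom_len); unclipped windows have length 2 * flank + 1 (501 bases at
#' the default flank of 250).
#'
#' @param summit absolute 0-based summit position(s)
#' @param flank bases on each side (default 250)
#' @param chrom_len chromosome length for clipping (default Inf)
#' @return data.frame with columns start, end (0-based half-open)
#' @export
summit_window <- function(summit, flank = 250L, chrom_len = Inf) {
  stopifnot(flank >= 0L)
  start <- pmax(0, summit - flank)
  end <- pmin(chrom_len, summit + flank + 1)
  data.frame(start = start, end = end)
}

.window_granges <- function(df, flank, chrom_lens = NULL) {
  lens <- if (is.null(chrom_lens)) rep(Inf, nrow(df)) else
    unname(chrom_lens[df$chrom])
  w <- summit_window(df$summit, flank = flank, chrom_len = lens)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = w$start + 1L, end = w$end))
}

#' Extract summit-window sequences from a genome
#'
#' One uppercase sequence per peak, in peak order; windows are clipped at
#' chromosome boundaries.
#'
#' @param ps a \code{\link{peak_set}}
#' @param genome named \code{Biostrings::DNAStringSet} or named character
#'   vector of chromosome sequences
#' @param flank window half-width (default 250)
#' @return character vector of sequences
#' @export
extract_window_sequences <- function(ps, genome, flank = 250L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  p <- ps$peaks
  missing <- setdiff(unique(p$chrom), names(genome))
  if (length(missing) > 0L) {
    stop("unknown chromosome: ", missing[1])
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    cl <- lens[[p$chrom[i]]]
    w <- summit_window(p$summit[i], flank = flank, chrom_len = cl)
    out[i] <- toupper(as.character(
      Biostrings::subseq(genome[[p$chrom[i]]], start = w$start + 1L,
                         end = w$end)))
  }
  out
}

#' Directional summit-window overlap percentage between two peak sets
#'
#' The percentage of the top-N peaks of \code{a} whose +/- flank summit
#' window intersects the summit window of at least one top-N peak of
#' \code{b}; each query peak counts at most once. Window intersection is
#' equivalent to a summit distance of at most 2 * flank. The alternative
#' reading — the summit of one peak falling inside the other's window
#' (distance <= flank) — is available as \code{mode = "summit_in_window"}.
#'
#' @param a,b \code{\link{peak_set}} objects (query and target)
#' @param n top-N cut (default 500)
#' @param flank window half-width (default 250)
#' @param mode overlap rule (default \code{"window"})
#' @return percentage in [0, 100]
#' @export
overlap_percentage <- function(a, b, n = 500L, flank = 250L,
                               mode = c("window", "summit_in_window")) {
  mode <- match.arg(mode)
  ta <- top_n_peaks(a, n)$peaks
  tb <- top_n_peaks(b, n)$peaks
  if (nrow(ta) == 0L || nrow(tb) == 0L) {
    stop("undefined overlap: empty top peak set")
  }
  fb <- if (mode == "window") flank else 0L
  ga <- .window_granges(ta, flank)
  gb <- .window_granges(tb, fb)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  100 * length(unique(S4Vectors::queryHits(hits))) / nrow(ta)
}

#' Remove peaks whose summit window touches a repeat annotation
#'
#' A peak is dropped if its summit window shares at least one base with any
#' annotated repeat interval (any-overlap rule). An empty annotation leaves
#' the set unchanged.
#'
#' @param ps a \code{\link{peak_set}}
#' @param repeats a \code{\link{repeat_annotation}}
#' @param flank window half-width (default 250)
#' @return filtered \code{\link{peak_set}}
#' @export
filter_non_ere <- function(ps, repeats, flank = 250L) {
  p <- ps$peaks
  if (nrow(p) == 0L || nrow(repeats$intervals) == 0L) return(ps)
  gw <- .window_granges(p, flank)
  gr <- .repeats_granges(repeats)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gw, gr))
  drop <- unique(S4Vectors::queryHits(hits))
  out <- if (length(drop) > 0L) p[-drop, , drop = FALSE] else p
  rownames(out) <- NULL
  peak_set(ps$protein, ps$dataset, out)
}
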