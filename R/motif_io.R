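#' Read PWMs from motif text
#'
#' Two dialects are supported. \code{meme_minimal} honours only the
#' \code{MEME version}, \code{ALPHABET=}, \code{MOTIF} and
#' \code{letter-probability matrix} lines; everything else is ignored.
#' \code{tsv_matrix} expects, per motif, a header line
#' \code{#name<TAB>width} followed by \code{width} rows of 4 tab-separated
#' probabilities.
#'
#' Rows whose sum deviates from 1 by at most 1e-3 are renormalized; larger
#' deviations raise a malformed-motif error naming the motif and row. An
#' empty file yields an empty list.
#'
#' @param text motif file content: a single string or a character vector of
#'   lines
#' @param format \code{"meme_minimal"} or \code{"tsv_matrix"}
#' @return list of \code{\link{pwm}} objects
#' @export
read_pwms <- function(text, format = c("meme_minimal", "tsv_matrix")) {
  format <- match.arg(format)
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  switch(format,
         meme_minimal = .read_meme_minimal(lines),
         tsv_matrix = .read_tsv_matrix(lines))
}

#' Read PWMs from a motif file
#' @param path file path
#' @inheritParams read_pwms
#' @return list of \code{\link{pwm}} objects
#' @export
read_pwms_file <- function(path, format = c("meme_minimal", "tsv_matrix")) {
  read_pwms(readLines(path, warn = FALSE), format = format)
}

.parse_prob_row <- function(line) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "[ \t]+")[[1]]))
  if (length(vals) != 4L || anyNA(vals)) return(NULL)
  vals
}

.read_meme_minimal <- function(lines) {
  pwms <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (startsWith(line, "MOTIF")) {
      name <- strsplit(line, "[ \t]+")[[1]][2]
      if (is.na(name)) name <- paste0("motif_", length(pwms) + 1L)
      # advance to the letter-probability matrix header
      j <- i + 1L
      while (j <= n && !startsWith(trimws(lines[j]), "letter-probability matrix")) {
        if (startsWith(trimws(lines[j]), "MOTIF")) {
          stop("malformed motif '", name, "': no letter-probability matrix")
        }
        j <- j + 1L
      }
      if (j > n) stop("malformed motif '", name, "': no letter-probability matrix")
      rows <- list()
      j <- j + 1L
      while (j <= n) {
        vals <- .parse_prob_row(lines[j])
        if (is.null(vals)) break
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (length(rows) == 0L) {
        stop("malformed motif '", name, "': empty probability matrix")
      }
      m <- do.call(rbind, rows)
      .check_rows(m, name)
      pwms[[length(pwms) + 1L]] <- pwm(name, m)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  pwms
}

.read_tsv_matrix <- function(lines) {
  pwms <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (startsWith(line, "#")) {
      parts <- strsplit(sub("^#", "", line), "\t", fixed = TRUE)[[1]]
      name <- parts[1]
      width <- suppressWarnings(as.integer(parts[2]))
      if (is.na(width) || width < 1L) {
        stop("malformed motif header at line ", i, ": '", line, "'")
      }
      if (i + width > n) stop("malformed motif '", name, "': truncated matrix")
      rows <- lapply(lines[(i + 1L):(i + width)], .parse_prob_row)
      if (any(vapply(rows, is.null, logical(1)))) {
        stop("malformed motif '", name, "': unparseable probability row")
      }
      m <- do.call(rbind, rows)
      .check_rows(m, name)
      pwms[[length(pwms) + 1L]] <- pwm(name, m)
      i <- i + width + 1L
    } else if (nzchar(line)) {
      stop("unexpected line ", i, " outside a motif block: '", line, "'")
    } else {
      i <- i + 1L
    }
  }
  pwms
}

.check_rows <- function(m, name, tol = 1e-3) {
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0L) {
    stop("malformed motif '", name, "': row ", off[1], " sums to ",
         format(rs[off[1]]), " (must be 1 within ", tol, ")")
  }
  invisible(TRUE)
}

#' Write PWMs as MEME minimal motif text
#'
#' Reading the output back reproduces the matrices to within 1e-6
#' elementwise. An empty list yields a header-only file.
#'
#' @param pwms list of \code{\link{pwm}} objects
#' @param path optional file path; when given, the text is also written there
#' @return the motif text, invisibly when \code{path} is given
#' @export
write_pwms <- function(pwms, path = NULL) {
  header <- c("MEME version 4", "", "ALPHABET= ACGT", "",
              "strands: + -", "")
  blocks <- unlist(lapply(pwms, function(x) {
    stopifnot(inherits(x, "pwm"))
    m <- x$matrix
    c(paste("MOTIF", x$name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              nrow(m)),
      apply(m, 1L, function(r) paste(sprintf("%.8f", r), collapse = " ")),
      "")
  }))
  text <- paste(c(header, blocks), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
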