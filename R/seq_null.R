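#' Dinucleotide-preserving sequence shuffle
#'
#' Returns a random permutation of \code{seq} with exactly the same multiset
#' of overlapping dinucleotides (hence the same length, first and last
#' characters, and mononucleotide counts), sampled by the Euler-path
#' construction of Altschul and Erickson: the dinucleotide graph's edges are
#' walked in random order after choosing, for every vertex but the terminal
#' one, a random designated last edge whose chosen set must form a tree into
#' the terminal vertex.
#'
#' Runs of N are frozen in place and the ACGT segments between them are
#' shuffled independently, preserving masked-region structure.
#'
#' @param seq nucleotide string (ACGTN)
#' @param seed integer seed for reproducibility, or NULL to use the current
#'   RNG stream
#' @return shuffled nucleotide string
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  with_seed(seed, {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    bad <- !(chars %in% c(DNA_BASES, "N"))
    if (any(bad)) stop("invalid character in sequence (alphabet is ACGTN)")
    is_n <- chars == "N"
    if (all(is_n)) return(seq)
    # split into maximal ACGT segments, shuffle each independently
    r <- rle(is_n)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) {
        seg <- chars[starts[i]:ends[i]]
        chars[starts[i]:ends[i]] <- .euler_shuffle(seg)
      }
    }
    paste(chars, collapse = "")
  })
}

# Altschul-Erickson shuffle of a vector of ACGT characters
.euler_shuffle <- function(chars) {
  n <- length(chars)
  if (n <= 2L) return(chars)
  codes <- match(chars, DNA_BASES)
  verts <- sort(unique(codes))
  if (length(verts) == 1L) return(chars)
  last <- codes[n]
  # out-edge target lists per vertex
  edges <- split(codes[-1L], codes[-n])
  edge_of <- function(v) edges[[as.character(v)]]
  nonterm <- setdiff(verts, last)
  # vertices with out-edges (every vertex except possibly the terminal has
  # at least one since it appears followed by something)
  repeat {
    # pick a random designated last edge for each non-terminal vertex
    last_edge <- vapply(nonterm, function(v) {
      e <- edge_of(v)
      e[sample.int(length(e), 1L)]
    }, integer(1))
    names(last_edge) <- as.character(nonterm)
    # the chosen edges must form a tree pointing into the terminal vertex:
    # from each vertex, following designated edges must reach `last`
    ok <- TRUE
    for (v in nonterm) {
      cur <- v
      steps <- 0L
      while (cur != last) {
        cur <- last_edge[[as.character(cur)]]
        steps <- steps + 1L
        if (steps > length(verts)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute remaining edges uniformly, append the designated last edge
  shuffled <- lapply(as.character(verts), function(vk) {
    e <- edges[[vk]]
    if (is.null(e)) return(integer(0))
    if (vk %in% names(last_edge)) {
      le <- last_edge[[vk]]
      drop_idx <- match(le, e)
      rest <- e[-drop_idx]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      c(rest, le)
    } else {
      if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  })
  names(shuffled) <- as.character(verts)
  ptr <- stats::setNames(rep(1L, length(verts)), as.character(verts))
  out <- integer(n)
  out[1L] <- codes[1L]
  cur <- codes[1L]
  for (i in 2:n) {
    k <- as.character(cur)
    nxt <- shuffled[[k]][ptr[[k]]]
    ptr[[k]] <- ptr[[k]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  DNA_BASES[out]
}

#' Census of overlapping dinucleotides
#'
#' Counts every overlapping 2-mer of the sequence; used to verify shuffle
#' conservation. N-containing 2-mers are counted like any other.
#'
#' @param seq nucleotide string
#' @return named integer vector of dinucleotide counts
#' @export
dinucleotide_census <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) return(stats::setNames(integer(0), character(0)))
  di <- paste0(chars[-length(chars)], chars[-1L])
  table_to_named_int(table(di))
}

table_to_named_int <- function(tb) {
  out <- as.integer(tb)
  names(out) <- names(tb)
  out[order(names(out))]
}

#' Random uniform background sequences
#'
#' Generates \code{n} i.i.d. uniform ACGT strings of length \code{l},
#' reproducible under \code{seed}.
#'
#' @param n number of sequences
#' @param l sequence length
#' @param seed integer seed or NULL
#' @return character vector of \code{n} sequences
#' @export
random_sequences <- function(n, l, seed = NULL) {
  stopifnot(n >= 1L, l >= 1L)
  with_seed(seed, {
    m <- matrix(sample(DNA_BASES, as.double(n) * l, replace = TRUE),
                nrow = n, ncol = l)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
}
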