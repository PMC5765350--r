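# shared fixtures and independent oracles for the test suite

one_hot_pwm <- function(name, consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <- 1
  pwm(name, m)
}

random_pwm <- function(name, width) {
  m <- matrix(stats::rgamma(width * 4, 1), nrow = width)
  pwm(name, m / rowSums(m))
}

random_dna <- function(l) {
  paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
}

# brute-force maximum log-odds window score, independent of the scanner
bf_max_score <- function(seq, sm, both_strands = TRUE) {
  score_one <- function(s) {
    w <- nrow(sm)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sapply(seq_len(nchar(s) - w + 1), function(off) {
      sum(sapply(seq_len(w), function(j) {
        b <- chars[off + j - 1]
        if (b == "N") 0 else sm[j, b]
      }))
    })
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }
  best <- max(score_one(seq))
  if (both_strands) best <- max(best, max(score_one(rc(seq))))
  best
}

# brute-force summed affinity, independent of the scanner
bf_affinity <- function(seq, x, both_strands = TRUE) {
  pm <- x$matrix
  w <- nrow(pm)
  score_one <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(sapply(seq_len(nchar(s) - w + 1), function(off) {
      prod(sapply(seq_len(w), function(j) {
        b <- chars[off + j - 1]
        if (b == "N") 0.25 else pm[j, b]
      }))
    }))
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }
  score_one(seq) + if (both_strands) score_one(rc(seq)) else 0
}

# brute-force pairwise-count AUROC oracle
bf_auroc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

make_peakset <- function(protein = "P", dataset = "d", chrom = "chr1",
                         starts, ends, scores = NULL, summits = NULL,
                         names = NULL) {
  k <- length(starts)
  if (is.null(scores)) scores <- rep(1, k)
  if (is.null(summits)) summits <- starts + (ends - starts) %/% 2L
  if (is.null(names)) names <- paste0("p", seq_len(k))
  peak_set(protein, dataset,
           data.frame(chrom = chrom, start = starts, end = ends,
                      name = names, score = scores, summit = summits))
}

make_profile <- function(protein, dataset, fractions) {
  structure(list(protein = protein, dataset = dataset,
                 fractions = fractions),
            class = "ere_profile")
}

# default-condition synthetic study, built once and shared across test files
.study_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- simulate_study(sim_config())
  }
  .study_cache$study
}

# per-protein AUROC grids of the default study (merged peaks, shared nulls)
default_grids <- function() {
  if (is.null(.study_cache$grids)) {
    study <- default_study()
    grids <- list()
    for (pi in seq_along(study$peaksets)) {
      prot <- names(study$peaksets)[pi]
      merged <- lapply(study$peaksets[[prot]], merge_peaks)
      grids[[prot]] <- evaluate_grid(study$candidates[[prot]], merged,
                                     study$genome,
                                     seed = motifconcord:::derive_seed(study$cfg$seed,
                                                        200L + pi))
    }
    .study_cache$grids <- grids
  }
  .study_cache$grids
}

# candidate table per protein of the default study
default_tables <- function() {
  grids <- default_grids()
  study <- default_study()
  lapply(names(grids), function(prot) {
    motifconcord:::.candidates_to_table(prot, study$candidates[[prot]],
                                        grids[[prot]])
  })
}

# the six-scenario hand fixture: one protein engineered per class A-F.
# Expected classes traced by hand from the rule order:
#  pA: trueA test 0.85, others <= 0.70 -> A
#  pB: no A (gap 0.05); in vitro 0.78 vs best ChIP 0.80 -> B
#  pC: no A (gap 0.05 between ChIPs), no in vitro; rcade ChIP present -> C
#  pD: no A/B/C (meme motifs, close test scores); one ChIP trains at 0.9
#      vs other's train 0.7 -> D
#  pE: no A/B/C (meme, test margin 0.05) and train margin 0.05 < 0.1 -> E
#  pF: single meme motif, no rule with a comparator applies -> F
handmade_tables <- function() {
  list(
    candidate_table("pA", list(
      motif_candidate("A_win", "meme", c(d1 = 0.80, d2 = 0.85), train = "d1"),
      motif_candidate("A_low", "meme", c(d1 = 0.70, d2 = 0.60), train = "d2"))),
    candidate_table("pB", list(
      motif_candidate("B_iv", "external", c(d1 = 0.78, d2 = 0.75),
                      is_in_vitro = TRUE),
      motif_candidate("B_chip", "meme", c(d1 = 0.70, d2 = 0.80), train = "d1"))),
    candidate_table("pC", list(
      motif_candidate("C_rcade", "rcade", c(d1 = 0.70, d2 = 0.72), train = "d1"),
      motif_candidate("C_meme", "meme", c(d1 = 0.69, d2 = 0.71), train = "d2"))),
    candidate_table("pD", list(
      motif_candidate("D_win", "meme", c(d1 = 0.90, d2 = 0.75), train = "d1"),
      motif_candidate("D_low", "meme", c(d1 = 0.78, d2 = 0.70), train = "d2"))),
    candidate_table("pE", list(
      motif_candidate("E_win", "meme", c(d1 = 0.76, d2 = 0.80), train = "d1"),
      motif_candidate("E_low", "meme", c(d1 = 0.75, d2 = 0.74), train = "d2"))),
    candidate_table("pF", list(
      motif_candidate("F_only", "meme", c(d1 = 0.70, d2 = 0.65), train = "d1"))))
}
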