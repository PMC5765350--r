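test_that("repeat annotations parse from BED+class and RepeatMasker tables", {
  ann <- read_repeats("chr1\t500\t900\tL1PA3")
  expect_equal(nrow(ann$intervals), 1L)
  expect_equal(ann$classes, "L1PA3")

  expect_equal(length(read_repeats("")$classes), 0L)

  ann <- read_repeats(c("chr1\t10\t20\tAlu", "chr1\t30\t40\tAlu"))
  expect_equal(ann$classes, "Alu")
  expect_equal(nrow(ann$intervals), 2L)

  rm_out <- c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end   (left)   repeat class/family",
    "",
    "  463  1.3  0.6  1.7  chr1      1001  1400 (100) +  L1PA3  LINE/L1   1 400 (0) 1",
    "  300  2.0  0.1  0.2  chr1      2001  2200 (100) C  AluY   SINE/Alu  1 200 (0) 2")
  ann <- read_repeats(rm_out, format = "repeatmasker_out")
  expect_equal(ann$intervals$start, c(1000L, 2000L))
  expect_equal(ann$intervals$end, c(1400L, 2200L))
  expect_equal(ann$classes, c("L1PA3", "AluY"))

  expect_error(read_repeats("chr1\t200\t100\tL1"), "malformed repeat interval")
})

test_that("ERE profiles are per-class window-overlap fractions", {
  # 5 peaks; 1 window hits L1, 1 spans both L1 and Alu, 3 hit nothing
  ann <- repeat_annotation(data.frame(
    chrom = "chr1",
    start = c(1000L, 1750L, 2100L),
    end = c(1500L, 2050L, 2400L),
    class = c("L1", "L1", "Alu")))
  ps <- make_peakset(starts = c(1100L, 1950L, 9000L, 12000L, 15000L),
                     ends = c(1200L, 2050L, 9100L, 12100L, 15100L),
                     summits = c(1150L, 2000L, 9050L, 12050L, 15050L))
  prof <- compute_profile(ps, ann, n = 500)
  expect_equal(prof$fractions[["L1"]], 2 / 5)
  expect_equal(prof$fractions[["Alu"]], 1 / 5)  # the spanning peak counts in both

  # peaks outside all repeats give the all-zero vector
  far <- make_peakset(starts = c(9000L, 12000L), ends = c(9100L, 12100L))
  expect_true(all(compute_profile(far, ann)$fractions == 0))

  empty <- peak_set("P", "d", data.frame(chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         name = character(0),
                                         score = numeric(0),
                                         summit = integer(0)))
  expect_error(compute_profile(empty, ann), "undefined profile")

  # only the top-N peaks enter the fractions
  scored <- make_peakset(starts = c(1100L, 9000L), ends = c(1200L, 9100L),
                         scores = c(1, 5))
  prof <- compute_profile(scored, ann, n = 1)
  expect_true(all(prof$fractions == 0))
})

test_that("profile correlation is Pearson with NA for degenerate vectors", {
  cls <- c("a", "b", "c")
  p <- make_profile("P", "d1", setNames(c(0.1, 0.2, 0.3), cls))
  q <- make_profile("P", "d2", setNames(c(0.3, 0.2, 0.1), cls))
  expect_equal(profile_correlation(p, p), 1.0)
  expect_equal(profile_correlation(p, q), -1.0)

  const <- make_profile("P", "d2", setNames(rep(0.2, 3), cls))
  expect_true(is.na(profile_correlation(p, const)))

  mis <- make_profile("P", "d2", setNames(c(0.1, 0.2, 0.3), rev(cls)))
  expect_error(profile_correlation(p, mis), "class orderings")

  # invariance under a common class permutation
  set.seed(2)
  for (i in 1:10) {
    f1 <- runif(6)
    f2 <- runif(6)
    perm <- sample(6)
    a1 <- make_profile("P", "d1", setNames(f1, letters[1:6]))
    a2 <- make_profile("P", "d2", setNames(f2, letters[1:6]))
    b1 <- make_profile("P", "d1", setNames(f1[perm], letters[1:6][perm]))
    b2 <- make_profile("P", "d2", setNames(f2[perm], letters[1:6][perm]))
    expect_equal(profile_correlation(a1, a2), profile_correlation(b1, b2))
  }
})

test_that("matched/unmatched decomposition yields k and C(2k,2)-k comparisons", {
  set.seed(4)
  mk_lists <- function(k, shared = 0) {
    base <- lapply(seq_len(k), function(i) runif(8))
    list(
      a = lapply(seq_len(k), function(i) {
        make_profile(paste0("P", i), "d1",
                     setNames(base[[i]] * shared + runif(8) * (1 - shared),
                              letters[1:8]))
      }),
      b = lapply(seq_len(k), function(i) {
        make_profile(paste0("P", i), "d2",
                     setNames(base[[i]] * shared + runif(8) * (1 - shared),
                              letters[1:8]))
      }))
  }
  # combinatorial identity for k = 2..50
  for (k in c(2:6, 20, 39, 50)) {
    l <- mk_lists(k)
    ag <- matched_vs_unmatched(l$a, l$b)
    expect_length(ag$matched_correlations, k)
    expect_length(ag$unmatched_correlations, choose(2 * k, 2) - k)
  }
  expect_error(matched_vs_unmatched(mk_lists(1)$a, mk_lists(1)$b),
               "insufficient proteins")

  # shared structure separates matched from unmatched at the chosen threshold
  l <- mk_lists(12, shared = 0.9)
  ag <- matched_vs_unmatched(l$a, l$b)
  expect_gt(ag$frac_matched_above, ag$frac_unmatched_above)
  # and the matched correlations stochastically dominate (one-sided MWU)
  p <- wilcox.test(ag$matched_correlations, ag$unmatched_correlations,
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)

  # fixed-threshold rule honours strict exceedance
  ag2 <- matched_vs_unmatched(l$a, l$b, threshold_rule = "fixed",
                              threshold = max(ag$matched_correlations))
  expect_equal(ag2$frac_matched_above, 0)
})

test_that("matched ERE agreement separates on the default synthetic study", {
  study <- default_study()
  merged <- lapply(study$peaksets, function(pp) lapply(pp, merge_peaks))
  pa <- lapply(merged, function(pp) compute_profile(pp$d1, study$repeats))
  pb <- lapply(merged, function(pp) compute_profile(pp$d2, study$repeats))
  ag <- matched_vs_unmatched(unname(pa), unname(pb))
  p <- wilcox.test(ag$matched_correlations, ag$unmatched_correlations,
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
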