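test_that("BED-dialect peak parsing resolves summits and rejects bad lines", {
  ps <- read_peaks("chr1\t100\t200\tp1\t9.5\t50")
  expect_equal(ps$peaks$summit, 150L)
  expect_equal(ps$peaks$score, 9.5)

  # sentinel -1 means interval midpoint
  ps <- read_peaks("chr1\t100\t200\tp1\t1\t-1")
  expect_equal(ps$peaks$summit, 150L)

  expect_error(read_peaks("chr1\t200\t100\tp1\t1\t50"),
               "malformed interval at line 1")
  expect_error(read_peaks("chr1\tabc\t100\tp1\t1\t0"), "non-integer")
  expect_equal(n <- nrow(read_peaks("")$peaks), 0L)

  # write -> read round trip
  ps <- make_peakset(starts = c(10L, 400L), ends = c(60L, 900L),
                     scores = c(3.5, 1.25), summits = c(30L, 700L))
  back <- read_peaks(write_peaks(ps))
  expect_equal(back$peaks[c("start", "end", "score", "summit")],
               ps$peaks[c("start", "end", "score", "summit")])
})

test_that("peak merging unions within the gap and inherits from the best member", {
  ps <- make_peakset(starts = c(100L, 240L), ends = c(200L, 300L))
  m <- merge_peaks(ps, max_gap = 50)   # gap 40 -> one peak
  expect_equal(nrow(m$peaks), 1L)
  expect_equal(m$peaks$start, 100L)
  expect_equal(m$peaks$end, 300L)

  ps <- make_peakset(starts = c(100L, 251L), ends = c(200L, 300L))
  expect_equal(nrow(merge_peaks(ps, max_gap = 50)$peaks), 2L)  # gap 51
  # boundary: gap exactly 50 merges
  ps <- make_peakset(starts = c(100L, 250L), ends = c(200L, 300L))
  expect_equal(nrow(merge_peaks(ps, max_gap = 50)$peaks), 1L)

  # merged score = max member score; summit from the highest-scoring member
  ps <- make_peakset(starts = c(100L, 150L), ends = c(200L, 260L),
                     scores = c(5, 9), summits = c(150L, 210L))
  m <- merge_peaks(ps)
  expect_equal(m$peaks$start, 100L)
  expect_equal(m$peaks$end, 260L)
  expect_equal(m$peaks$score, 9)
  expect_equal(m$peaks$summit, 210L)

  # idempotence and gap property on random peak sets
  set.seed(11)
  for (i in 1:10) {
    k <- sample(5:30, 1)
    starts <- sort(sample.int(5000, k))
    ps <- make_peakset(starts = starts, ends = starts + sample(20:120, k, TRUE),
                       scores = runif(k))
    m <- merge_peaks(ps)
    expect_equal(merge_peaks(m)$peaks[c("chrom", "start", "end")],
                 m$peaks[c("chrom", "start", "end")])
    p <- m$peaks
    if (nrow(p) > 1L) expect_true(all(p$start[-1] - p$end[-nrow(p)] > 50))
    expect_false(anyDuplicated(p[c("chrom", "start", "end")]) > 0)
  }
})

test_that("top-N selection keeps the highest scores with deterministic ties", {
  ps <- make_peakset(starts = c(1L, 100L, 200L) * 10L,
                     ends = c(1L, 100L, 200L) * 10L + 50L,
                     scores = c(1, 2, 3))
  expect_equal(nrow(top_n_peaks(ps, 500)$peaks), 3L)  # fewer than N -> all

  set.seed(3)
  starts <- seq(0L, by = 100L, length.out = 1000L)
  ps <- make_peakset(starts = starts, ends = starts + 50L, scores = runif(1000))
  top <- top_n_peaks(ps, 500)
  expect_equal(nrow(top$peaks), 500L)
  expect_true(all(diff(top$peaks$score) <= 0))
  expect_gte(min(top$peaks$score), max(setdiff(ps$peaks$score, top$peaks$score)))

  # equal scores at the rank boundary: earlier (chrom, start) wins
  ps <- make_peakset(starts = c(500L, 100L), ends = c(550L, 150L),
                     scores = c(1, 1))
  expect_equal(top_n_peaks(ps, 1)$peaks$start, 100L)
})

test_that("summit windows have length 2*flank+1 and clip at boundaries", {
  w <- summit_window(1000L, flank = 250)
  expect_equal(w$end - w$start, 501)
  expect_equal(c(w$start, w$end), c(750, 1251))
  w <- summit_window(100L, flank = 250)
  expect_equal(c(w$start, w$end), c(0, 351))
  w <- summit_window(100L, flank = 0)
  expect_equal(c(w$start, w$end), c(100, 101))
  w <- summit_window(990L, flank = 250, chrom_len = 1000L)
  expect_equal(c(w$start, w$end), c(740, 1000))
})

test_that("window sequence extraction slices the genome and flags bad chroms", {
  set.seed(5)
  chrom <- random_dna(10000)
  genome <- c(chr1 = chrom)
  ps <- make_peakset(starts = 4000L, ends = 4500L, summits = 4250L)
  seqs <- extract_window_sequences(ps, genome)
  expect_equal(seqs, substr(chrom, 4001, 4501))
  expect_equal(nchar(seqs), 501L)

  near <- make_peakset(starts = 0L, ends = 100L, summits = 50L)
  expect_equal(nchar(extract_window_sequences(near, genome)), 301L)

  off <- make_peakset(chrom = "chrX", starts = 10L, ends = 50L)
  expect_error(extract_window_sequences(off, genome), "unknown chromosome: chrX")
})

test_that("overlap percentage follows summit-window intersection arithmetic", {
  a <- make_peakset(starts = c(1000L, 3000L), ends = c(1100L, 3100L))
  expect_equal(overlap_percentage(a, a), 100)

  b <- make_peakset(chrom = "chr2", starts = c(1000L, 3000L),
                    ends = c(1100L, 3100L))
  expect_equal(overlap_percentage(a, b), 0)

  # windows of two summits 400 apart intersect (<= 2*flank = 500); 600 do not
  x <- make_peakset(starts = 1000L, ends = 1100L, summits = 1050L)
  y400 <- make_peakset(starts = 1400L, ends = 1500L, summits = 1450L)
  y600 <- make_peakset(starts = 1600L, ends = 1700L, summits = 1650L)
  expect_equal(overlap_percentage(x, y400), 100)
  expect_equal(overlap_percentage(x, y600), 0)
  # boundary: distance exactly 500 still intersects, 501 does not
  expect_equal(overlap_percentage(x, make_peakset(starts = 1500L, ends = 1600L,
                                                  summits = 1550L)), 100)
  expect_equal(overlap_percentage(x, make_peakset(starts = 1501L, ends = 1601L,
                                                  summits = 1551L)), 0)
  # the alternative summit-in-window reading uses distance <= flank
  expect_equal(overlap_percentage(x, y400, mode = "summit_in_window"), 0)

  # directionality
  big <- make_peakset(starts = c(1000L, 5000L), ends = c(1100L, 5100L))
  one <- make_peakset(starts = 1000L, ends = 1100L)
  expect_equal(overlap_percentage(big, one), 50)
  expect_equal(overlap_percentage(one, big), 100)

  empty <- peak_set("P", "d", data.frame(chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         name = character(0),
                                         score = numeric(0),
                                         summit = integer(0)))
  expect_error(overlap_percentage(empty, a), "undefined overlap")

  # shifting a copy beyond 2*flank drives overlap to zero
  shifted <- a
  shifted$peaks$start <- shifted$peaks$start + 10000L
  shifted$peaks$end <- shifted$peaks$end + 10000L
  shifted$peaks$summit <- shifted$peaks$summit + 10000L
  expect_equal(overlap_percentage(a, shifted), 0)
})

test_that("non-ERE filtering drops any window touching a repeat", {
  rep_ann <- repeat_annotation(data.frame(chrom = "chr1", start = 1000L,
                                          end = 1400L, class = "L1"))
  inside <- make_peakset(starts = 1100L, ends = 1200L, summits = 1150L)
  expect_equal(nrow(filter_non_ere(inside, rep_ann)$peaks), 0L)

  # window [649, 1150) shares exactly 1 bp iff summit = 1400 - 251... use
  # summit such that window end = repeat start + 1
  touch <- make_peakset(starts = 700L, ends = 800L, summits = 750L)
  # window [500, 1001) overlaps [1000, 1400) by 1 base -> removed
  expect_equal(nrow(filter_non_ere(touch, rep_ann)$peaks), 0L)
  clear <- make_peakset(starts = 700L, ends = 760L, summits = 749L)
  # window [499, 1000) does not touch [1000, 1400) -> kept
  expect_equal(nrow(filter_non_ere(clear, rep_ann)$peaks), 1L)

  none <- repeat_annotation(data.frame(chrom = character(0), start = integer(0),
                                       end = integer(0), class = character(0)))
  expect_equal(filter_non_ere(inside, none)$peaks, inside$peaks)

  # brute-force cross check on random configurations
  set.seed(17)
  for (i in 1:5) {
    starts <- sample.int(50000, 40)
    ps <- make_peakset(starts = starts, ends = starts + 100L)
    rs <- sample.int(50000, 15)
    ann <- repeat_annotation(data.frame(chrom = "chr1", start = rs,
                                        end = rs + sample(50:500, 15, TRUE),
                                        class = "R"))
    kept <- filter_non_ere(ps, ann)$peaks
    overlaps_any <- function(summit) {
      ws <- max(0, summit - 250)
      we <- summit + 251
      any(ws < ann$intervals$end & we > ann$intervals$start)
    }
    expect_true(all(!vapply(kept$summit, overlaps_any, logical(1))))
    dropped <- setdiff(ps$peaks$summit, kept$summit)
    expect_true(all(vapply(dropped, overlaps_any, logical(1))))
  }
})
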