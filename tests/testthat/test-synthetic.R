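test_that("the generator is fully deterministic under its seed", {
  cfg <- sim_config(n_proteins = 2, genome_length = 200000,
                    n_ere_classes = 4, ere_copies_per_class = 8,
                    true_site_pool_size = 50, peaks_per_dataset = 30,
                    seed = 19)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$repeats$intervals, s2$repeats$intervals)
  expect_identical(s1$peaksets, s2$peaksets)
  expect_identical(lapply(s1$candidates, function(l) lapply(l, `[[`, "matrix")),
                   lapply(s2$candidates, function(l) lapply(l, `[[`, "matrix")))
})

test_that("the ERE library has the right shape and near-random divergence", {
  cfg <- sim_config(n_ere_classes = 5, ere_length = 300)
  lib <- generate_ere_library(cfg, seed = 3)
  expect_length(lib, 5L)
  expect_true(all(nchar(lib) == 300L))
  expect_identical(lib, generate_ere_library(cfg, seed = 3))
  # pairwise identity of independent random sequences is ~25%, well under 60%
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(ident(lib[[i]], lib[[j]]), 0.6)
  }
})

test_that("the genome carries every annotated ERE copy at the set divergence", {
  cfg <- sim_config(n_proteins = 1, genome_length = 500000,
                    n_ere_classes = 5, ere_copies_per_class = 10)
  g <- generate_genome(cfg, seed = 7)
  expect_equal(nrow(g$repeats$intervals), 50L)
  expect_equal(sort(table(g$repeats$intervals$class)),
               sort(table(rep(names(g$ere_library), 10))))
  # intervals do not overlap
  iv <- g$repeats$intervals[order(g$repeats$intervals$start), ]
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))

  # mutation rate 0: every copy identical to its consensus
  g0 <- generate_genome(sim_config(copy_mutation_rate = 0,
                                   genome_length = 500000,
                                   n_ere_classes = 5,
                                   ere_copies_per_class = 10), seed = 7)
  gen <- paste(g0$genome_chars, collapse = "")
  for (i in seq_len(nrow(g0$repeats$intervals))) {
    iv <- g0$repeats$intervals[i, ]
    expect_equal(substr(gen, iv$start + 1, iv$end),
                 unname(g0$ere_library[[iv$class]]))
  }

  # observed per-copy substitution fraction tracks the configured rate
  gen <- paste(g$genome_chars, collapse = "")
  rates <- vapply(seq_len(nrow(g$repeats$intervals)), function(i) {
    iv <- g$repeats$intervals[i, ]
    copy <- strsplit(substr(gen, iv$start + 1, iv$end), "")[[1]]
    cons <- strsplit(g$ere_library[[iv$class]], "")[[1]]
    mean(copy != cons)
  }, numeric(1))
  sd3 <- 3 * sqrt(0.1 * 0.9 / cfg$ere_length)
  expect_lt(abs(mean(rates) - 0.1), sd3)

  expect_error(generate_genome(sim_config(genome_length = 50000), seed = 1),
               "overcrowded genome")
})

test_that("protein ground truth plants retrievable consensus sites", {
  cfg <- sim_config(n_proteins = 3, genome_length = 400000,
                    n_ere_classes = 4, ere_copies_per_class = 10,
                    true_site_pool_size = 80)
  g <- generate_genome(cfg, seed = 13)
  tr <- generate_protein_truth(cfg, g, seed = 13)
  expect_length(tr$truth, 3L)
  gen <- paste(tr$genome_chars, collapse = "")
  for (prot in names(tr$truth)) {
    t <- tr$truth[[prot]]
    expect_length(t$sites, 80L)
    # information-rich columns
    expect_true(all(apply(t$pwm$matrix, 1, max) >= 0.8))
    expect_true(all(t$ere_classes %in% g$repeats$classes))
    # planted consensus scores near the maximum attainable log-odds
    sm <- to_score_matrix(t$pwm)
    max_attain <- sum(apply(sm, 1, max))
    w <- nrow(sm)
    for (s in t$sites[1:10]) {
      site_seq <- substr(gen, s + 1, s + w)
      expect_gte(max_pwm_score(site_seq, sm), 0.95 * max_attain)
    }
    # ERE-assigned sites lie inside intervals of the assigned classes
    iv <- g$repeats$intervals[g$repeats$intervals$class %in% t$ere_classes, ]
    inside <- vapply(t$sites[t$site_in_ere], function(s) {
      any(s >= iv$start & s + w <= iv$end)
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("paired peak sets share true sites at the hypergeometric rate", {
  cfg <- sim_config(n_proteins = 1, genome_length = 400000,
                    n_ere_classes = 4, ere_copies_per_class = 10,
                    true_site_pool_size = 200, peaks_per_dataset = 150,
                    false_peak_fraction = 0.2)
  g <- generate_genome(cfg, seed = 17)
  tr <- generate_protein_truth(cfg, g, seed = 17)
  # expected sharing: 120 true peaks drawn twice from a 200-site pool
  site_ids <- function(ps) {
    nm <- ps$peaks$name
    sub(".*_true_", "", nm[grepl("_true_", nm)])
  }
  shared <- vapply(1:20, function(s) {
    pks <- generate_peaksets(cfg, tr, seed = s)$P01
    length(intersect(site_ids(pks$d1), site_ids(pks$d2)))
  }, numeric(1))
  expn <- 120^2 / 200
  sd_hyper <- sqrt(120 * (120 / 200) * (80 / 200) * (200 - 120) / 199)
  expect_lt(abs(mean(shared) - expn), 3 * sd_hyper)

  # false_peak_fraction 0 with pool = peaks: both datasets cover every site
  cfg0 <- sim_config(n_proteins = 1, genome_length = 400000,
                     n_ere_classes = 4, ere_copies_per_class = 10,
                     true_site_pool_size = 50, peaks_per_dataset = 50,
                     false_peak_fraction = 0)
  g0 <- generate_genome(cfg0, seed = 23)
  tr0 <- generate_protein_truth(cfg0, g0, seed = 23)
  pks <- generate_peaksets(cfg0, tr0, seed = 23)$P01
  expect_equal(nrow(pks$d1$peaks), 50L)
  expect_true(all(grepl("_true_", pks$d1$peaks$name)))
  expect_true(all(grepl("_true_", pks$d2$peaks$name)))

  # pool exhaustion is an error
  cfg_bad <- sim_config(n_proteins = 1, genome_length = 400000,
                        n_ere_classes = 4, ere_copies_per_class = 10,
                        true_site_pool_size = 20, peaks_per_dataset = 50,
                        false_peak_fraction = 0)
  g2 <- generate_genome(cfg_bad, seed = 5)
  tr2 <- generate_protein_truth(cfg_bad, g2, seed = 5)
  expect_error(generate_peaksets(cfg_bad, tr2, seed = 5), "pool exhausted")
})

test_that("candidate motifs span true, corrupted and unrelated decoys", {
  cfg <- sim_config(n_proteins = 2, genome_length = 300000,
                    n_ere_classes = 4, ere_copies_per_class = 8,
                    true_site_pool_size = 50, peaks_per_dataset = 30,
                    include_in_vitro = TRUE)
  g <- generate_genome(cfg, seed = 29)
  tr <- generate_protein_truth(cfg, g, seed = 29)
  cands <- generate_candidate_motifs(cfg, tr, seed = 29)
  expect_length(cands$P01, 4L)
  nms <- vapply(cands$P01, function(m) m$name, character(1))
  expect_setequal(nms, c("P01_true", "P01_corrupt", "P01_decoy", "P01_invitro"))
  # the decoy is the other protein's matrix
  expect_equal(cands$P01[[3]]$matrix, tr$truth$P02$pwm$matrix)

  # corruption fraction 0 keeps the matrix; 1 gives the uniform motif
  cfg0 <- sim_config(n_proteins = 1, genome_length = 300000,
                     n_ere_classes = 4, ere_copies_per_class = 8,
                     true_site_pool_size = 50, corruption_fraction = 0)
  c0 <- generate_candidate_motifs(cfg0, tr, seed = 1)
  expect_equal(c0$P01[[2]]$matrix, tr$truth$P01$pwm$matrix)
  cfg1 <- sim_config(n_proteins = 1, genome_length = 300000,
                     n_ere_classes = 4, ere_copies_per_class = 8,
                     true_site_pool_size = 50, corruption_fraction = 1)
  c1 <- generate_candidate_motifs(cfg1, tr, seed = 1)
  expect_true(all(c1$P01[[2]]$matrix == 0.25))

  # the corrupted decoy loses AUROC to the true motif
  wins <- vapply(1:20, function(s) {
    study <- simulate_study(sim_config(n_proteins = 2, genome_length = 300000,
                                       n_ere_classes = 4,
                                       ere_copies_per_class = 8,
                                       true_site_pool_size = 60,
                                       peaks_per_dataset = 40,
                                       corruption_fraction = 0.5, seed = s))
    ps <- study$peaksets$P01$d1
    nulls <- shuffle_windows(extract_window_sequences(top_n_peaks(ps, 500),
                                                      study$genome), seed = s)
    a_true <- evaluate_motif(study$candidates$P01[[1]], ps, study$genome,
                             shuffled_seqs = nulls)
    a_corr <- evaluate_motif(study$candidates$P01[[2]], ps, study$genome,
                             shuffled_seqs = nulls)
    a_true > a_corr
  }, logical(1))
  expect_gte(sum(wins), 18L)
})
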