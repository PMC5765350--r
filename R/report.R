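#' Write a synthetic study to disk
#'
#' Materializes a \code{\link{simulate_study}} result as the plain-text
#' formats the pipeline consumes: FASTA genome, BED+class repeat
#' annotation, one BED-dialect peak file per protein and dataset, a MEME
#' minimal file of all candidate motifs with a metadata TSV sidecar, a
#' ground-truth site table, and a manifest echoing the configuration and
#' listing every file written. Identical seeds give byte-identical trees.
#'
#' @param study a \code{sim_study} from \code{\link{simulate_study}}
#' @param outdir output directory (created if needed)
#' @return invisibly, the manifest lines
#' @export
run_simulate <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  genome <- Biostrings::DNAStringSet(study$genome)
  Biostrings::writeXStringSet(genome, filepath = file.path(outdir, "genome.fa"))
  files <- c(files, "genome.fa")
  write_repeats(study$repeats, file.path(outdir, "repeats.bed"))
  files <- c(files, "repeats.bed")
  for (prot in names(study$peaksets)) {
    for (ds in names(study$peaksets[[prot]])) {
      fn <- sprintf("peaks_%s_%s.tsv", prot, ds)
      write_peaks(study$peaksets[[prot]][[ds]], file.path(outdir, fn))
      files <- c(files, fn)
    }
  }
  all_motifs <- unlist(study$candidates, recursive = FALSE)
  write_pwms(all_motifs, file.path(outdir, "motifs.meme"))
  files <- c(files, "motifs.meme")
  meta <- vapply(all_motifs, function(m) {
    md <- m$metadata
    paste(m$name, md$protein, md$source, md$method,
          md$recognition_code_supported, md$is_in_vitro, sep = "\t")
  }, character(1))
  writeLines(c("motif\tprotein\tsource\tmethod\trecognition_code_supported\tis_in_vitro",
               meta), file.path(outdir, "motif_metadata.tsv"))
  files <- c(files, "motif_metadata.tsv")
  gt <- do.call(rbind, lapply(names(study$truth), function(prot) {
    tr <- study$truth[[prot]]
    data.frame(protein = prot, site = tr$sites, in_ere = tr$site_in_ere,
               classes = paste(tr$ere_classes, collapse = ","))
  }))
  utils::write.table(gt, file.path(outdir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, "ground_truth.tsv")
  cfg_echo <- paste(names(study$cfg), unlist(lapply(study$cfg, format)),
                    sep = " = ")
  manifest <- c("# synthetic study manifest", cfg_echo, "# files", files,
                "manifest.txt")
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(manifest)
}

#' Compare the two datasets of a synthetic study
#'
#' Runs the full comparison over every protein with both peak sets: merged
#' top-N summit-window overlap percentages in both directions (for all
#' peaks and for the top N), ERE enrichment profiles per peak set plus the
#' matched-versus-unmatched agreement summary, one affinity-correlation
#' similarity matrix over all candidate motifs on a shared background, and
#' per-protein AUROC grids of each candidate on both peak sets (motifs
#' within a peak set share one shuffled null). Also assembles the candidate
#' tables consumed by the selection step.
#'
#' @param study a \code{sim_study}
#' @param n_top top-N cut (default 500)
#' @param flank summit window half-width (default 250)
#' @param merge_gap peak-merge gap in bp (default 50)
#' @param sim_n,sim_l similarity background size (defaults 100000, 100)
#' @param seed master seed for shuffles and the similarity background
#'   (default: the study's seed)
#' @param outdir optional directory for TSV reports
#' @return a \code{compare_result} list
#' @export
run_compare <- function(study, n_top = 500L, flank = 250L, merge_gap = 50L,
                        sim_n = 100000L, sim_l = 100L, seed = study$cfg$seed,
                        outdir = NULL) {
  genome <- study$genome
  prots <- names(study$peaksets)
  merged <- lapply(study$peaksets, function(pp) {
    lapply(pp[!vapply(pp, is.null, logical(1))], merge_peaks,
           max_gap = merge_gap)
  })
  paired <- prots[vapply(merged, function(pp) {
    all(c("d1", "d2") %in% names(pp))
  }, logical(1))]
  # directional overlap percentages; missing where a dataset is absent
  overlaps <- do.call(rbind, lapply(prots, function(prot) {
    if (!(prot %in% paired)) {
      return(data.frame(protein = prot, d1_vs_d2_top = NA_real_,
                        d2_vs_d1_top = NA_real_, d1_vs_d2_all = NA_real_,
                        d2_vs_d1_all = NA_real_))
    }
    a <- merged[[prot]]$d1
    b <- merged[[prot]]$d2
    data.frame(protein = prot,
               d1_vs_d2_top = overlap_percentage(a, b, n = n_top, flank = flank),
               d2_vs_d1_top = overlap_percentage(b, a, n = n_top, flank = flank),
               d1_vs_d2_all = overlap_percentage(a, b, n = .Machine$integer.max,
                                                 flank = flank),
               d2_vs_d1_all = overlap_percentage(b, a, n = .Machine$integer.max,
                                                 flank = flank))
  }))
  # ERE profiles and matched-vs-unmatched agreement (paired proteins only)
  profiles_a <- lapply(paired, function(prot) {
    compute_profile(merged[[prot]]$d1, study$repeats, n = n_top, flank = flank)
  })
  profiles_b <- lapply(paired, function(prot) {
    compute_profile(merged[[prot]]$d2, study$repeats, n = n_top, flank = flank)
  })
  agreement <- if (length(paired) >= 2L) {
    matched_vs_unmatched(profiles_a, profiles_b)
  } else NULL
  # similarity over all candidates on one shared background
  all_motifs <- unlist(study$candidates, recursive = FALSE)
  simmat <- similarity_matrix(all_motifs, n = sim_n, l = sim_l,
                              seed = derive_seed(seed, 101L))
  # per-protein AUROC grids; one shuffled null per peak set
  grids <- list()
  tables <- list()
  for (pi in seq_along(prots)) {
    prot <- prots[pi]
    grids[[prot]] <- evaluate_grid(study$candidates[[prot]], merged[[prot]],
                                   genome, seed = derive_seed(seed, 200L + pi),
                                   n = n_top, flank = flank)
    tables[[prot]] <- .candidates_to_table(prot, study$candidates[[prot]],
                                           grids[[prot]])
  }
  res <- structure(list(overlaps = overlaps,
                        profiles_d1 = profiles_a, profiles_d2 = profiles_b,
                        agreement = agreement,
                        similarity = simmat,
                        auroc_grids = grids,
                        candidate_tables = tables),
                   class = "compare_result")
  if (!is.null(outdir)) .write_compare(res, study, outdir)
  res
}

.candidates_to_table <- function(prot, motifs, grid) {
  cands <- lapply(motifs, function(m) {
    md <- m$metadata
    train <- if (md$method %in% c("rcade", "meme") && !md$is_in_vitro) {
      md$source
    } else NA_character_
    motif_candidate(m$name, method = md$method,
                    aurocs = grid[m$name, ],
                    train = train,
                    is_in_vitro = md$is_in_vitro,
                    recognition_code_supported = md$recognition_code_supported)
  })
  candidate_table(prot, cands)
}

.write_compare <- function(res, study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$overlaps, file.path(outdir, "overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof_mat <- rbind(
    do.call(rbind, lapply(res$profiles_d1, function(p) p$fractions)),
    do.call(rbind, lapply(res$profiles_d2, function(p) p$fractions)))
  rownames(prof_mat) <- c(
    vapply(res$profiles_d1, function(p) paste0(p$protein, "_d1"), character(1)),
    vapply(res$profiles_d2, function(p) paste0(p$protein, "_d2"), character(1)))
  utils::write.table(prof_mat, file.path(outdir, "ere_profiles.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(res$agreement)) {
    ag <- res$agreement
    writeLines(c(sprintf("matched_comparisons\t%d", length(ag$matched_correlations)),
                 sprintf("unmatched_comparisons\t%d", length(ag$unmatched_correlations)),
                 sprintf("threshold\t%.6f", ag$threshold),
                 sprintf("frac_matched_above\t%.6f", ag$frac_matched_above),
                 sprintf("frac_unmatched_above\t%.6f", ag$frac_unmatched_above)),
               file.path(outdir, "ere_agreement.tsv"))
  }
  write_similarity_matrix(res$similarity, file.path(outdir, "similarity.tsv"))
  grid_rows <- unlist(lapply(names(res$auroc_grids), function(prot) {
    g <- res$auroc_grids[[prot]]
    unlist(lapply(rownames(g), function(m) {
      vapply(colnames(g), function(ds) {
        paste(prot, m, ds,
              ifelse(is.na(g[m, ds]), "", sprintf("%.6f", g[m, ds])),
              sep = "\t")
      }, character(1))
    }))
  }))
  writeLines(c("protein\tmotif\tpeakset\tauroc", grid_rows),
             file.path(outdir, "auroc_grid.tsv"))
  invisible(outdir)
}

#' Select reference motifs from a comparison result
#'
#' Applies the class A-F decision procedure to every protein's candidate
#' table, fills in cross-source similarity confidence metrics, and
#' optionally writes the reference TSV, the chosen motifs as a MEME minimal
#' file, and a sidecar listing unselectable proteins.
#'
#' @param compare a \code{compare_result} from \code{\link{run_compare}}
#' @param study the \code{sim_study} the comparison was run on (for the
#'   chosen PWMs)
#' @param th a \code{\link{selection_thresholds}}
#' @param outdir optional output directory
#' @return a \code{reference_set}
#' @export
run_select <- function(compare, study, th = selection_thresholds(),
                       outdir = NULL) {
  ref <- build_reference_set(compare$candidate_tables,
                             similarity = compare$similarity, th = th)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_reference_set(ref, file.path(outdir, "reference.tsv"))
    all_motifs <- unlist(study$candidates, recursive = FALSE)
    names(all_motifs) <- vapply(all_motifs, function(m) m$name, character(1))
    chosen <- unlist(lapply(ref$results, function(r) r$chosen))
    write_pwms(all_motifs[chosen], file.path(outdir, "reference_motifs.meme"))
    if (length(ref$errors) > 0L) {
      writeLines(paste(names(ref$errors), ref$errors, sep = "\t"),
                 file.path(outdir, "unselectable.tsv"))
    }
  }
  ref
}
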