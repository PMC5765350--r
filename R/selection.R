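#' Selection thresholds
#'
#' Numeric constants of the reference-motif decision rules: the AUROC margin
#' a uniquely predictive motif must clear (class A and D), the largest gap at
#' which an in vitro motif still counts as matching the ChIP motifs (class
#' B), the small-margin band of class E, the AUROC quality bar, the two
#' similarity interpretation levels, and the two cross-dataset disagreement
#' cutoffs (ERE profile r and motif similarity r).
#'
#' @param class_a_margin AUROC margin for classes A and D (default 0.1)
#' @param class_b_gap maximum in-vitro-vs-ChIP AUROC gap for class B
#'   (strict; default 0.1)
#' @param class_e_range closed AUROC-margin interval for class E
#'   (default c(0.01, 0.09))
#' @param auc_quality_bar AUROC above which a motif is considered enriched
#'   (default 0.6)
#' @param similarity_same,similarity_related similarity levels (0.5, 0.2)
#' @param ere_disagreement,motif_disagreement strict lower cutoffs flagging
#'   cross-dataset disagreement (0.3, 0.2)
#' @return a \code{selection_thresholds} list
#' @export
selection_thresholds <- function(class_a_margin = 0.1, class_b_gap = 0.1,
                                 class_e_range = c(0.01, 0.09),
                                 auc_quality_bar = 0.6,
                                 similarity_same = 0.5,
                                 similarity_related = 0.2,
                                 ere_disagreement = 0.3,
                                 motif_disagreement = 0.2) {
  stopifnot(length(class_e_range) == 2L,
            class_e_range[1] <= class_e_range[2])
  if (class_e_range[2] >= class_a_margin) {
    stop("class E upper bound must be below the class A margin")
  }
  structure(list(class_a_margin = class_a_margin, class_b_gap = class_b_gap,
                 class_e_range = class_e_range,
                 auc_quality_bar = auc_quality_bar,
                 similarity_same = similarity_same,
                 similarity_related = similarity_related,
                 ere_disagreement = ere_disagreement,
                 motif_disagreement = motif_disagreement),
            class = "selection_thresholds")
}

#' Candidate motif entry for selection
#'
#' One candidate motif of a protein with its evaluation record. ChIP-derived
#' candidates name the peak set they were trained on; all other peak sets
#' with an AUROC count as test sets. In vitro and external candidates have
#' no training set, so every evaluated peak set is a test set.
#'
#' @param name motif identifier
#' @param method \code{"rcade"}, \code{"meme"} or \code{"external"}
#' @param aurocs named numeric vector of AUROCs per peak-set label
#' @param train label of the training peak set, or NA for in
#'   vitro/external motifs
#' @param is_in_vitro logical
#' @param recognition_code_supported logical; forced TRUE for rcade
#' @return a \code{motif_candidate} list
#' @export
motif_candidate <- function(name, method = c("rcade", "meme", "external"),
                            aurocs = numeric(0), train = NA_character_,
                            is_in_vitro = FALSE,
                            recognition_code_supported = FALSE) {
  method <- match.arg(method)
  if (method == "rcade") recognition_code_supported <- TRUE
  chip <- method %in% c("rcade", "meme") && !is_in_vitro
  if (chip && (is.na(train) || !nzchar(train))) {
    stop("ChIP-derived candidate '", name, "' needs exactly one train set")
  }
  if (!chip) train <- NA_character_
  structure(list(name = name, method = method, aurocs = aurocs,
                 train = train, is_in_vitro = isTRUE(is_in_vitro),
                 recognition_code_supported = isTRUE(recognition_code_supported),
                 is_chip = chip),
            class = "motif_candidate")
}

#' Candidate table for one protein
#' @param protein protein identifier
#' @param candidates list of \code{\link{motif_candidate}} objects
#' @return a \code{candidate_table}
#' @export
candidate_table <- function(protein, candidates) {
  stopifnot(length(candidates) >= 1L,
            all(vapply(candidates, inherits, logical(1), "motif_candidate")))
  structure(list(protein = protein, candidates = candidates),
            class = "candidate_table")
}

.test_score <- function(cand) {
  a <- cand$aurocs[setdiff(names(cand$aurocs),
                           if (is.na(cand$train)) character(0) else cand$train)]
  a <- a[!is.na(a)]
  if (length(a) == 0L) NA_real_ else max(a)
}

.train_score <- function(cand) {
  if (is.na(cand$train) || !(cand$train %in% names(cand$aurocs))) {
    return(NA_real_)
  }
  v <- cand$aurocs[[cand$train]]
  if (is.na(v)) NA_real_ else v
}

# tie policy: higher test score, then rcade > meme > external, then name
.pick_best <- function(cands, scores) {
  method_rank <- c(rcade = 1L, meme = 2L, external = 3L)
  ord <- order(-scores,
               method_rank[vapply(cands, function(c) c$method, character(1))],
               vapply(cands, function(c) c$name, character(1)))
  cands[[ord[1]]]
}

#' Assign a selection class (A-F) to a protein's candidate motifs
#'
#' Rules are evaluated in order. A: some candidate's best test AUROC exceeds
#' every other test-scored candidate's by at least the class-A margin. B (no
#' A): the best in vitro candidate's test AUROC is within the class-B gap of
#' (or better than) the best ChIP candidate's. C (no A/B): a
#' recognition-code-supported ChIP candidate exists; the one with the
#' highest test score wins (training score as fallback when it has no test
#' set). D: some ChIP candidate's training AUROC exceeds all other
#' candidates' training AUROCs by the margin. E: the best-vs-second-best
#' test margin lies in the closed class-E band. F: everything else; all
#' remaining candidates are reported as co-equal.
#'
#' Rules A, D and E need at least one *other* scored candidate to compare
#' against, so a single-candidate protein falls through to F unless class C
#' applies.
#'
#' @param table a \code{\link{candidate_table}}
#' @param th a \code{\link{selection_thresholds}}
#' @return a \code{selection_result}: protein, chosen motif name(s), class,
#'   best test AUROC, method
#' @export
assign_class <- function(table, th = selection_thresholds()) {
  stopifnot(inherits(table, "candidate_table"))
  cands <- table$candidates
  scored <- cands[vapply(cands, function(c) any(!is.na(c$aurocs)), logical(1))]
  if (length(scored) == 0L) {
    stop("unselectable protein '", table$protein, "': no candidate has an AUROC")
  }
  tests <- vapply(scored, .test_score, numeric(1))
  trains <- vapply(scored, .train_score, numeric(1))

  result <- function(chosen, cls) {
    if (inherits(chosen, "motif_candidate")) chosen <- list(chosen)
    structure(list(
      protein = table$protein,
      chosen = vapply(chosen, function(c) c$name, character(1)),
      selection_class = cls,
      best_test_auroc = {
        v <- vapply(chosen, .test_score, numeric(1))
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      },
      best_cross_source_similarity = NA_real_,
      method = vapply(chosen, function(c) c$method, character(1))),
      class = "selection_result")
  }

  # Class A: uniquely predictive of test peaks
  has_test <- which(!is.na(tests))
  if (length(has_test) >= 2L) {
    for (i in has_test) {
      others <- tests[setdiff(has_test, i)]
      if (all(tests[i] >= others + th$class_a_margin)) {
        return(result(scored[[i]], "A"))
      }
    }
  }
  # Class B: in vitro motif predictive of test peaks
  iv <- which(vapply(scored, function(c) c$is_in_vitro, logical(1)) &
                !is.na(tests))
  chip <- which(vapply(scored, function(c) c$is_chip, logical(1)) &
                  !is.na(tests))
  if (length(iv) > 0L && length(chip) > 0L) {
    best_iv <- max(tests[iv])
    best_chip <- max(tests[chip])
    if (best_chip - best_iv < th$class_b_gap) {
      winners <- scored[iv[tests[iv] == best_iv]]
      return(result(.pick_best(winners, rep(best_iv, length(winners))), "B"))
    }
  }
  # Class C: recognition-code-supported ChIP motif
  rc <- which(vapply(scored, function(c) c$recognition_code_supported &&
                       c$is_chip, logical(1)))
  if (length(rc) > 0L) {
    sc <- ifelse(is.na(tests[rc]), trains[rc], tests[rc])
    winners <- scored[rc[!is.na(sc) & sc == max(sc, na.rm = TRUE)]]
    if (length(winners) > 0L) {
      return(result(.pick_best(winners,
                               rep(max(sc, na.rm = TRUE), length(winners))),
                    "C"))
    }
  }
  # Class D: uniquely predictive of its own training peaks
  has_train <- which(!is.na(trains))
  chip_train <- which(!is.na(trains) &
                        vapply(scored, function(c) c$is_chip, logical(1)))
  if (length(chip_train) >= 1L && length(has_train) >= 2L) {
    for (i in chip_train) {
      others <- trains[setdiff(has_train, i)]
      if (length(others) > 0L &&
          all(trains[i] >= others + th$class_a_margin)) {
        return(result(scored[[i]], "D"))
      }
    }
  }
  # Class E: slightly better on test peaks than the rest
  if (length(has_test) >= 2L) {
    srt <- sort(tests[has_test], decreasing = TRUE)
    margin <- srt[1] - srt[2]
    if (margin >= th$class_e_range[1] && margin <= th$class_e_range[2]) {
      winners <- scored[has_test[tests[has_test] == srt[1]]]
      return(result(.pick_best(winners, rep(srt[1], length(winners))), "E"))
    }
  }
  # Class F: everything else, co-equal
  result(scored, "F")
}

#' Cross-dataset disagreement flags
#'
#' An experiment pair disagrees on EREs bound when the ERE-profile
#' correlation is strictly below the ERE cutoff, and on motifs when the
#' motif similarity is strictly below the motif cutoff. A missing input
#' leaves its flag absent.
#'
#' @param ere_r ERE-profile Pearson correlation (or NA)
#' @param motif_r motif similarity (or NA)
#' @param th a \code{\link{selection_thresholds}}
#' @return character vector, subset of
#'   \code{c("ere_disagrees", "motif_disagrees")}
#' @export
flag_disagreement <- function(ere_r, motif_r, th = selection_thresholds()) {
  flags <- character(0)
  if (!is.na(ere_r) && ere_r < th$ere_disagreement) {
    flags <- c(flags, "ere_disagrees")
  }
  if (!is.na(motif_r) && motif_r < th$motif_disagreement) {
    flags <- c(flags, "motif_disagrees")
  }
  flags
}

#' Build the reference motif set over many proteins
#'
#' Runs \code{\link{assign_class}} per protein, collecting per-protein
#' errors instead of failing, and populates each result's best
#' cross-source similarity (the chosen motif's highest similarity to any
#' other motif in the matrix). Also reports class counts and the median best
#' test AUROC per class.
#'
#' @param tables list of \code{\link{candidate_table}} objects
#' @param similarity optional \code{similarity_matrix} over the candidate
#'   motifs
#' @param th a \code{\link{selection_thresholds}}
#' @return a \code{reference_set}: results, class_counts,
#'   class_median_auroc, errors (named character of failures)
#' @export
build_reference_set <- function(tables, similarity = NULL,
                                th = selection_thresholds()) {
  results <- list()
  errors <- character(0)
  for (tab in tables) {
    res <- tryCatch(assign_class(tab, th), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[tab$protein]] <- conditionMessage(res)
      next
    }
    if (!is.null(similarity)) {
      m <- similarity
      best <- suppressWarnings(max(vapply(res$chosen, function(nm) {
        if (!(nm %in% rownames(m))) return(NA_real_)
        v <- m[nm, setdiff(colnames(m), nm)]
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      }, numeric(1)), na.rm = TRUE))
      res$best_cross_source_similarity <- if (is.finite(best)) best else NA_real_
    }
    results[[res$protein]] <- res
  }
  classes <- vapply(results, function(r) r$selection_class, character(1))
  counts <- table(factor(classes, levels = LETTERS[1:6]))
  med <- vapply(LETTERS[1:6], function(cl) {
    v <- vapply(results[classes == cl], function(r) r$best_test_auroc,
                numeric(1))
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  structure(list(results = results,
                 class_counts = table_to_named_int(counts),
                 class_median_auroc = med,
                 errors = errors),
            class = "reference_set")
}

#' Write a reference set as TSV
#' @param ref a \code{reference_set}
#' @param path output file
#' @export
write_reference_set <- function(ref, path) {
  rows <- vapply(ref$results, function(r) {
    paste(r$protein, paste(r$chosen, collapse = ","), r$selection_class,
          paste(r$method, collapse = ","),
          ifelse(is.na(r$best_test_auroc), "",
                 format(r$best_test_auroc, digits = 4)),
          ifelse(is.na(r$best_cross_source_similarity), "",
                 format(r$best_cross_source_similarity, digits = 4)),
          sep = "\t")
  }, character(1))
  writeLines(c("protein\tmotif\tclass\tmethod\tbest_test_auroc\tbest_similarity",
               rows), path)
  invisible(path)
}
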