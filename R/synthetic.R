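#' Simulation configuration
#'
#' Parameters of the synthetic study: a background genome carrying mutated
#' copies of ERE consensus families (common-descent structure), per-protein
#' information-rich motifs planted inside and outside assigned ERE classes,
#' and two noisy peak sets per protein sampled from one shared pool of true
#' sites — so pairwise peak overlap is partial while ERE profiles and motifs
#' agree, the regime the comparison framework assumes.
#'
#' @param n_proteins number of proteins (default 10)
#' @param n_ere_classes number of ERE families (default 10)
#' @param ere_copies_per_class genomic copies per family (default 30)
#' @param ere_length family consensus length in bp (default 300)
#' @param copy_mutation_rate per-base substitution probability applied to
#'   each genomic copy (default 0.1)
#' @param genome_length single-chromosome genome size in bp (default 2e6)
#' @param motif_width planted motif width (default 8)
#' @param sites_per_protein alias of \code{true_site_pool_size}
#' @param true_site_pool_size shared pool of bona fide sites per protein
#'   (default 200)
#' @param peaks_per_dataset peaks per protein per dataset (default 150)
#' @param false_peak_fraction fraction of false peaks per dataset
#'   (default 0.3)
#' @param summit_jitter_sd Gaussian summit jitter, bases (default 20)
#' @param score_noise_sd Gaussian enrichment-score noise (default 2)
#' @param ere_site_fraction fraction of each protein's true sites placed
#'   inside its assigned ERE classes (default 0.6)
#' @param corruption_fraction fraction of decoy-motif columns replaced by
#'   uniform (default 0.75)
#' @param include_in_vitro also generate a near-true "in vitro" candidate
#'   motif per protein (default FALSE)
#' @param seed master seed (default 1)
#' @return a \code{sim_config} list
#' @export
sim_config <- function(n_proteins = 10L, n_ere_classes = 10L,
                       ere_copies_per_class = 30L, ere_length = 300L,
                       copy_mutation_rate = 0.1, genome_length = 2e6,
                       motif_width = 8L,
                       sites_per_protein = NULL,
                       true_site_pool_size = 200L,
                       peaks_per_dataset = 150L,
                       false_peak_fraction = 0.3,
                       summit_jitter_sd = 20,
                       score_noise_sd = 2,
                       ere_site_fraction = 0.6,
                       corruption_fraction = 0.75,
                       include_in_vitro = FALSE,
                       seed = 1L) {
  if (!is.null(sites_per_protein)) true_site_pool_size <- sites_per_protein
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_ere_classes = as.integer(n_ere_classes),
              ere_copies_per_class = as.integer(ere_copies_per_class),
              ere_length = as.integer(ere_length),
              copy_mutation_rate = copy_mutation_rate,
              genome_length = as.integer(genome_length),
              motif_width = as.integer(motif_width),
              true_site_pool_size = as.integer(true_site_pool_size),
              peaks_per_dataset = as.integer(peaks_per_dataset),
              false_peak_fraction = false_peak_fraction,
              summit_jitter_sd = summit_jitter_sd,
              score_noise_sd = score_noise_sd,
              ere_site_fraction = ere_site_fraction,
              corruption_fraction = corruption_fraction,
              include_in_vitro = isTRUE(include_in_vitro),
              seed = as.integer(seed))
  counts <- cfg[c("n_proteins", "n_ere_classes", "ere_copies_per_class",
                  "ere_length", "genome_length", "motif_width",
                  "true_site_pool_size", "peaks_per_dataset")]
  if (any(unlist(counts) < 1L)) stop("all counts must be positive")
  probs <- cfg[c("copy_mutation_rate", "false_peak_fraction",
                 "ere_site_fraction", "corruption_fraction")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("rates and fractions must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Generate ERE family consensus sequences
#' @param cfg a \code{\link{sim_config}}
#' @param seed seed (default: from cfg)
#' @return named character vector of consensus sequences
#' @export
generate_ere_library <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    seqs <- random_sequences(cfg$n_ere_classes, cfg$ere_length)
    stats::setNames(seqs, sprintf("ERE%02d", seq_len(cfg$n_ere_classes)))
  })
}

# mutate a character vector of bases by i.i.d. substitution
.mutate_bases <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  chars
}

#' Generate a synthetic genome with planted ERE copies
#'
#' An i.i.d. uniform background chromosome ("chr1") into which
#' non-overlapping mutated copies of each ERE family are placed uniformly at
#' random; each copy is the family consensus with i.i.d. substitutions at
#' \code{copy_mutation_rate}. The annotation records every copy with its
#' class.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param seed seed (default: from cfg)
#' @return list: \code{genome_chars} (character vector of bases),
#'   \code{repeats} (\code{\link{repeat_annotation}}), \code{ere_library}
#' @export
generate_genome <- function(cfg, seed = cfg$seed) {
  library_seqs <- generate_ere_library(cfg, seed = derive_seed(seed, 1L))
  with_seed(derive_seed(seed, 2L), {
    L <- cfg$genome_length
    n_copies <- cfg$n_ere_classes * cfg$ere_copies_per_class
    if (n_copies * cfg$ere_length > L) {
      stop("overcrowded genome: planted ERE material exceeds genome length")
    }
    genome <- sample(DNA_BASES, L, replace = TRUE)
    # non-overlapping uniform placement with bounded rejection
    occupied_start <- integer(0)
    occupied_end <- integer(0)
    placements <- vector("list", n_copies)
    max_tries <- 50L * n_copies
    tries <- 0L
    placed <- 0L
    while (placed < n_copies) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("overcrowded genome: could not place ERE copies without overlap")
      }
      s <- sample.int(L - cfg$ere_length, 1L)
      e <- s + cfg$ere_length
      if (any(s < occupied_end & e > occupied_start)) next
      placed <- placed + 1L
      occupied_start <- c(occupied_start, s)
      occupied_end <- c(occupied_end, e)
      placements[[placed]] <- c(s, e)
    }
    cls_idx <- rep(seq_len(cfg$n_ere_classes), each = cfg$ere_copies_per_class)
    intervals <- data.frame(chrom = "chr1",
                            start = vapply(placements, `[`, integer(1), 1L),
                            end = vapply(placements, `[`, integer(1), 2L),
                            class = names(library_seqs)[cls_idx])
    for (i in seq_len(n_copies)) {
      copy <- strsplit(library_seqs[[cls_idx[i]]], "", fixed = TRUE)[[1]]
      copy <- .mutate_bases(copy, cfg$copy_mutation_rate)
      genome[(intervals$start[i] + 1L):intervals$end[i]] <- copy
    }
    intervals <- intervals[order(intervals$start), , drop = FALSE]
    rownames(intervals) <- NULL
    list(genome_chars = genome,
         repeats = repeat_annotation(intervals),
         ere_library = library_seqs)
  })
}

# an information-rich random PWM: per column a consensus base with
# probability in [0.8, 0.95], remainder split over the other bases
.random_rich_pwm <- function(width) {
  m <- matrix(0, nrow = width, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(width)) {
    cons <- sample.int(4L, 1L)
    p <- stats::runif(1L, 0.8, 0.95)
    rest <- stats::runif(3L)
    rest <- rest / sum(rest) * (1 - p)
    m[i, cons] <- p
    m[i, -cons] <- rest
  }
  m
}

pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 1L, which.max)], collapse = "")
}

#' Generate per-protein ground truth and plant binding sites
#'
#' Each protein receives an information-rich random PWM (per-column maximum
#' probability at least 0.8) and 1-3 assigned ERE classes. Its shared pool
#' of true sites mixes positions inside copies of those classes with
#' non-repeat positions; the motif consensus is written into the genome at
#' every site.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param genome output of \code{\link{generate_genome}}
#' @param seed seed (default: from cfg)
#' @return list: \code{truth} (per protein: pwm, sites, ere_classes,
#'   site_in_ere), \code{genome_chars} (with sites planted)
#' @export
generate_protein_truth <- function(cfg, genome, seed = cfg$seed) {
  with_seed(derive_seed(seed, 3L), {
    chars <- genome$genome_chars
    L <- length(chars)
    w <- cfg$motif_width
    rep_iv <- genome$repeats$intervals
    margin <- 300L  # keep summit windows clear of chromosome ends
    # sites planted so far (all proteins): no two may overlap, so every
    # planted consensus stays intact and retrievable
    used_start <- integer(0)
    collides <- function(s) any(s < used_start + w & s + w > used_start)
    truth <- list()
    for (p in seq_len(cfg$n_proteins)) {
      prot <- sprintf("P%02d", p)
      x <- pwm(paste0(prot, "_true"), .random_rich_pwm(w),
               motif_metadata(protein = prot, source = "d1", method = "rcade"))
      n_cls <- sample(1:3, 1L)
      cls <- sample(genome$repeats$classes, n_cls)
      pool <- cfg$true_site_pool_size
      n_ere <- round(cfg$ere_site_fraction * pool)
      iv <- rep_iv[rep_iv$class %in% cls &
                     rep_iv$start >= margin &
                     rep_iv$end <= L - margin, , drop = FALSE]
      sites <- integer(0)
      in_ere <- logical(0)
      max_tries <- 200L * pool
      tries <- 0L
      if (nrow(iv) > 0L) {
        while (length(sites) < n_ere) {
          tries <- tries + 1L
          if (tries > max_tries) {
            stop("overcrowded genome: could not place non-overlapping sites")
          }
          i <- sample.int(nrow(iv), 1L)
          s <- iv$start[i] + sample.int(iv$end[i] - iv$start[i] - w + 1L, 1L) - 1L
          if (collides(s)) next
          sites <- c(sites, s)
          in_ere <- c(in_ere, TRUE)
          used_start <- c(used_start, s)
        }
      }
      while (length(sites) < pool) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("overcrowded genome: could not place non-overlapping sites")
        }
        s <- sample.int(L - 2L * margin, 1L) + margin
        if (any(s < rep_iv$end & s + w > rep_iv$start)) next
        if (collides(s)) next
        sites <- c(sites, s)
        in_ere <- c(in_ere, FALSE)
        used_start <- c(used_start, s)
      }
      cons <- strsplit(pwm_consensus(x), "", fixed = TRUE)[[1]]
      for (s in sites) chars[(s + 1L):(s + w)] <- cons
      truth[[prot]] <- list(pwm = x, sites = sites, ere_classes = cls,
                            site_in_ere = in_ere)
    }
    list(truth = truth, genome_chars = chars)
  })
}

#' Generate two noisy peak sets per protein
#'
#' Each dataset independently samples its true peaks (without replacement)
#' from the protein's shared site pool and fills the rest with false peaks
#' at uniform non-site positions. Summits are the site centre plus Gaussian
#' jitter; enrichment scores are Gaussian with a higher base signal for true
#' peaks, so true peaks dominate the top-N ranking without separating
#' perfectly.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param truth output of \code{\link{generate_protein_truth}}
#' @param seed seed (default: from cfg)
#' @return named list per protein of named lists (\code{d1}, \code{d2}) of
#'   \code{\link{peak_set}} objects; each peak table carries an
#'   \code{is_true} column in its attributes via name prefixes
#'   ("true"/"false")
#' @export
generate_peaksets <- function(cfg, truth, seed = cfg$seed) {
  with_seed(derive_seed(seed, 4L), {
    L <- cfg$genome_length
    w <- cfg$motif_width
    n_true <- round((1 - cfg$false_peak_fraction) * cfg$peaks_per_dataset)
    n_false <- cfg$peaks_per_dataset - n_true
    out <- list()
    for (prot in names(truth$truth)) {
      tr <- truth$truth[[prot]]
      if (n_true > length(tr$sites)) {
        stop("pool exhausted: ", n_true, " true peaks requested from a pool of ",
             length(tr$sites))
      }
      mk <- function(dataset) {
        # true-peak names carry the pool-site index so sharing between the
        # two datasets is measurable exactly
        site_idx <- sample.int(length(tr$sites), n_true)
        centers_true <- tr$sites[site_idx] + w %/% 2L
        centers_false <- sample.int(L - 600L, n_false) + 300L
        centers <- c(centers_true, centers_false)
        is_true <- rep(c(TRUE, FALSE), c(n_true, n_false))
        summits <- round(centers + stats::rnorm(length(centers),
                                                sd = cfg$summit_jitter_sd))
        summits <- pmin(pmax(summits, 251L), L - 252L)
        scores <- stats::rnorm(length(centers), sd = cfg$score_noise_sd) +
          ifelse(is_true, 10, 6)
        labels <- c(sprintf("%s_%s_true_s%d", prot, dataset, site_idx),
                    sprintf("%s_%s_false_%d", prot, dataset,
                            seq_len(n_false)))
        df <- data.frame(chrom = "chr1",
                         start = summits - 250L,
                         end = summits + 251L,
                         name = labels,
                         score = scores,
                         summit = summits)
        peak_set(prot, dataset, df)
      }
      out[[prot]] <- list(d1 = mk("d1"), d2 = mk("d2"))
    }
    out
  })
}

# Dirichlet-like small perturbation of a probability row
.perturb_row <- function(row, conc = 200) {
  g <- stats::rgamma(4L, shape = row * conc + 1e-3)
  g / sum(g)
}

#' Generate candidate motifs per protein
#'
#' For every protein: the true PWM (recognition-code-supported, trained on
#' d1), a corrupted decoy (a fraction of columns replaced by uniform,
#' trained on d2), another protein's true PWM relabelled as an external
#' candidate, and optionally a near-true "in vitro" motif (small Dirichlet
#' perturbation of the true matrix).
#'
#' @param cfg a \code{\link{sim_config}}
#' @param truth output of \code{\link{generate_protein_truth}}
#' @param seed seed (default: from cfg)
#' @return named list per protein of lists of \code{\link{pwm}} objects
#' @export
generate_candidate_motifs <- function(cfg, truth, seed = cfg$seed) {
  with_seed(derive_seed(seed, 5L), {
    prots <- names(truth$truth)
    out <- list()
    for (i in seq_along(prots)) {
      prot <- prots[i]
      true_pwm <- truth$truth[[prot]]$pwm
      w <- nrow(true_pwm$matrix)
      # corrupted decoy
      m <- true_pwm$matrix
      n_corrupt <- round(cfg$corruption_fraction * w)
      if (n_corrupt > 0L) {
        cols <- sample.int(w, n_corrupt)
        m[cols, ] <- 0.25
      }
      corrupt <- pwm(paste0(prot, "_corrupt"), m,
                     motif_metadata(protein = prot, source = "d2",
                                    method = "meme"))
      # another protein's motif as an unrelated external decoy
      other <- prots[if (i == length(prots)) 1L else i + 1L]
      decoy <- pwm(paste0(prot, "_decoy"), truth$truth[[other]]$pwm$matrix,
                   motif_metadata(protein = prot, source = "external:decoy",
                                  method = "external"))
      cand <- list(true_pwm, corrupt, decoy)
      if (cfg$include_in_vitro) {
        mv <- t(apply(true_pwm$matrix, 1L, .perturb_row))
        cand <- c(cand, list(
          pwm(paste0(prot, "_invitro"), mv,
              motif_metadata(protein = prot, source = "external:invitro",
                             method = "external", is_in_vitro = TRUE))))
      }
      out[[prot]] <- cand
    }
    out
  })
}

#' Run the full synthetic-study generator
#'
#' Chains genome, ground-truth, peak-set and candidate-motif generation
#' under one master seed. Byte-identical output for identical seeds.
#'
#' @param cfg a \code{\link{sim_config}}
#' @return a \code{sim_study}: cfg, genome (named character), repeats,
#'   ere_library, truth, peaksets, candidates
#' @export
simulate_study <- function(cfg = sim_config()) {
  g <- generate_genome(cfg)
  tr <- generate_protein_truth(cfg, g)
  peaksets <- generate_peaksets(cfg, tr)
  candidates <- generate_candidate_motifs(cfg, tr)
  genome <- stats::setNames(paste(tr$genome_chars, collapse = ""), "chr1")
  structure(list(cfg = cfg, genome = genome, repeats = g$repeats,
                 ere_library = g$ere_library, truth = tr$truth,
                 peaksets = peaksets, candidates = candidates),
            class = "sim_study")
}
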