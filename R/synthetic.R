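# Synthetic-data generators with known ground truth: NB counts with a
# planted differentially expressed fraction, promoter sequences with
# planted CpG islands and motif instances, and Ct tables with known fold
# changes.  All randomness derives from one integer seed per generator.

random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Simulate an NB count matrix with planted differential expression
#'
#' Gene base means are drawn log-uniform over `mean_range`; a
#' `de_fraction` of genes receives a log2 fold change drawn Normal(0,
#' `lfc_sd`) truncated to `|lfc| >= 0.3` and applied to condition B.  Each
#' count is NB with mean `base * 2^(lfc * [B]) * depth` and variance
#' `mean + dispersion * mean^2` (Poisson when dispersion is 0).
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per condition (>= 2; default 3).
#' @param de_fraction fraction of genes that are truly DE (default 0.1).
#' @param lfc_sd SD of the planted log2 fold changes (default 1.5).
#' @param dispersion NB dispersion, scalar or per-gene vector (default
#'   0.1; 0 gives Poisson counts).
#' @param mean_range base-mean range for the log-uniform draw (default
#'   c(1, 1e4)).
#' @param depth_factors per-sample depth multipliers (length `2 *
#'   n_reps`); NULL (default) draws them log-uniform over \[2/3, 3/2\].
#' @param conditions two condition labels (default c("ICM", "TE")).
#' @param seed integer seed.
#' @return object of class `sim_counts`: `counts` (integer matrix),
#'   `condition` (factor), `truth` (gene, base_mean, log2fc, is_de,
#'   dispersion), `depth_factors`, `seed`.
#' @export
simulate_counts <- function(n_genes, n_reps = 3L, de_fraction = 0.1,
                            lfc_sd = 1.5, dispersion = 0.1,
                            mean_range = c(1, 1e4), depth_factors = NULL,
                            conditions = c("ICM", "TE"), seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(n_reps, "n_reps")
  if (n_reps < 2L) stop("'n_reps' must be >= 2")
  if (de_fraction < 0 || de_fraction > 1) {
    stop("'de_fraction' must lie in [0, 1]")
  }
  if (any(dispersion < 0)) stop("'dispersion' must be non-negative")
  n_samp <- 2L * n_reps
  disp <- rep_len(dispersion, n_genes)
  with_seed(seed, {
    base <- exp(runif(n_genes, log(mean_range[1L]), log(mean_range[2L])))
    lfc <- rep(0, n_genes)
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    if (n_de > 0) {
      draw <- rnorm(n_de, 0, lfc_sd)
      while (any(small <- abs(draw) < 0.3)) {
        draw[small] <- rnorm(sum(small), 0, lfc_sd)
      }
      lfc[de_idx] <- draw
    }
    depth <- depth_factors %||% exp(runif(n_samp, log(2 / 3), log(3 / 2)))
    if (length(depth) != n_samp) {
      stop("'depth_factors' must have length 2 * n_reps")
    }
    cond <- factor(rep(conditions, each = n_reps), levels = conditions)
    mu <- outer(base, depth) *
      2^(outer(lfc, as.numeric(cond == conditions[2L])))
    counts <- matrix(0L, n_genes, n_samp)
    for (i in seq_len(n_genes)) {
      counts[i, ] <- if (disp[i] > 0) {
        as.integer(rnbinom(n_samp, mu = mu[i, ], size = 1 / disp[i]))
      } else {
        as.integer(rpois(n_samp, mu[i, ]))
      }
    }
    genes <- sprintf("gene%05d", seq_len(n_genes))
    dimnames(counts) <- list(genes,
                             paste0(rep(conditions, each = n_reps), "_",
                                    rep(seq_len(n_reps), 2L)))
    structure(list(
      counts = counts,
      condition = setNames(cond, colnames(counts)),
      truth = data.frame(gene = genes, base_mean = base, log2fc = lfc,
                         is_de = lfc != 0, dispersion = disp,
                         stringsAsFactors = FALSE),
      depth_factors = setNames(depth, colnames(counts)),
      seed = seed
    ), class = "sim_counts")
  })
}

# One CpG-dense tract that classifies positive on its central 200-base
# window: a dinucleotide process emitting "CG" with probability cg_rate,
# otherwise a single base at gc 0.6.  Regenerates until the island
# criterion holds (virtually always on the first draw).
make_island_tract <- function(len, cg_rate = 0.2, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    out <- character(0)
    while (sum(nchar(out)) < len) {
      out <- c(out, if (runif(1) < cg_rate) "CG" else {
        sample(c("A", "C", "G", "T"), 1L, prob = c(0.2, 0.3, 0.3, 0.2))
      })
    }
    s <- substr(paste(out, collapse = ""), 1L, len)
    mid <- substr(s, (len - 200L) %/% 2L + 1L, (len - 200L) %/% 2L + 200L)
    if (classify_cpg(gc_content(mid), cpg_score(mid))) return(s)
  }
  stop("failed to generate a CpG-positive tract")   # not reachable in practice
}

# Draw one motif instance from the PWM's per-column corrected base
# probabilities.
sample_motif_instance <- function(pwm) {
  paste(vapply(seq_len(pwm$length), function(j) {
    sample(rownames(pwm$probs), 1L, prob = pwm$probs[, j])
  }, character(1)), collapse = "")
}

#' Simulate promoter sequences with planted islands and motifs
#'
#' Each gene gets its own contig of length `2 * flank` with the TSS at its
#' center and a random strand.  An `island_fraction` of genes receives a
#' CpG-dense tract covering the -110/+110 region (so the -100/+100 window
#' classifies CpG-positive by construction); `planted_per_motif` genes per
#' motif receive one instance drawn from the motif's per-column base
#' probabilities, inserted inside the -200/+50 window (clear of the island
#' region for island genes) on a random strand.
#'
#' @param n_genes number of genes.
#' @param flank bases each side of the TSS (>= 250).
#' @param gc_background background GC proportion (default 0.4).
#' @param island_fraction fraction of genes given a planted island.
#' @param motif_models list of `pfm`/`pwm_model` objects to plant.
#' @param planted_per_motif instances planted per motif (default 0).
#' @param motif_genes optional pool of gene ids eligible for planting
#'   (default: all genes).
#' @param gene_ids optional gene identifiers.
#' @param seed integer seed.
#' @return object of class `sim_promoters`: `sequences` (named character,
#'   one contig per gene), `tss` (gene, chrom, tss, strand), `islands`
#'   (gene, start, end relative to the TSS), `motifs` (motif, gene,
#'   offset within the -200/+50 window, strand, instance), `seed`.
#' @export
simulate_promoters <- function(n_genes, flank = 300L, gc_background = 0.4,
                               island_fraction = 0, motif_models = NULL,
                               planted_per_motif = 0L, motif_genes = NULL,
                               gene_ids = NULL, seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes")
  if (flank < 250L) stop("'flank' must be >= 250")
  if (island_fraction < 0 || island_fraction > 1) {
    stop("'island_fraction' must lie in [0, 1]")
  }
  pwms <- lapply(motif_models %||% list(), pwm_from_pfm)
  for (p in pwms) {
    if (p$length > 250L) stop("motif longer than the -200/+50 window")
  }
  with_seed(seed, {
    genes <- gene_ids %||% sprintf("gene%05d", seq_len(n_genes))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    L <- 2L * flank
    oriented <- vapply(seq_len(n_genes), function(i) random_dna(L, gc_background),
                       character(1))
    names(oriented) <- genes

    n_isl <- round(island_fraction * n_genes)
    isl_genes <- if (n_isl > 0) sample(genes, n_isl) else character(0)
    for (g in isl_genes) {
      tract <- make_island_tract(220L)
      substr(oriented[g], flank - 110L + 1L, flank + 110L) <- tract
    }
    islands <- data.frame(gene = isl_genes,
                          start = rep(-110L, length(isl_genes)),
                          end = rep(110L, length(isl_genes)),
                          stringsAsFactors = FALSE)

    motif_rows <- list()
    pool <- motif_genes %||% genes
    for (p in pwms) {
      if (planted_per_motif < 1L) break
      if (planted_per_motif > length(pool)) {
        stop("planted_per_motif exceeds the eligible gene pool")
      }
      chosen <- sample(pool, planted_per_motif)
      for (g in chosen) {
        # offsets are 0-based within the -200/+50 window
        max_off <- if (g %in% isl_genes) 85L - p$length else 250L - p$length
        if (max_off < 0L) {
          stop("motif too long to plant clear of the island region; ",
               "use non-island genes in 'motif_genes'")
        }
        off <- sample.int(max_off + 1L, 1L) - 1L
        inst <- sample_motif_instance(p)
        inst_strand <- sample(c("+", "-"), 1L)
        text <- if (inst_strand == "-") revcomp(inst) else inst
        abs_start <- flank - 200L + off          # 0-based in the contig
        substr(oriented[g], abs_start + 1L, abs_start + p$length) <- text
        motif_rows[[length(motif_rows) + 1L]] <-
          data.frame(motif = p$id, gene = g, offset = off,
                     strand = inst_strand, instance = inst,
                     stringsAsFactors = FALSE)
      }
    }
    motifs <- if (length(motif_rows)) {
      do.call(rbind, motif_rows)
    } else {
      data.frame(motif = character(0), gene = character(0),
                 offset = integer(0), strand = character(0),
                 instance = character(0))
    }

    sequences <- oriented
    tss_pos <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      if (strand[i] == "+") {
        tss_pos[i] <- flank
      } else {
        sequences[i] <- revcomp(oriented[i])
        tss_pos[i] <- flank - 1L     # mirror of the TSS base in L = 2*flank
      }
    }
    structure(list(sequences = sequences,
                   tss = data.frame(gene = genes, chrom = genes,
                                    tss = tss_pos, strand = strand,
                                    stringsAsFactors = FALSE),
                   islands = islands, motifs = motifs,
                   flank = flank, seed = seed),
              class = "sim_promoters")
  })
}

#' Simulate a long-format Ct table with known fold changes
#'
#' Target genes are shifted by `-log2(true_fold)` cycles in the second
#' group relative to the first (the calibrator); reference genes are
#' unshifted.  Gaussian noise with SD `noise_sd` is added to every
#' measurement.
#'
#' @param n_per_group samples per group (default 6).
#' @param targets character vector of target gene ids.
#' @param refs character vector of reference gene ids (non-empty).
#' @param true_fold per-target fold change of group 2 vs group 1 (> 0,
#'   recycled).
#' @param noise_sd measurement noise in Ct units (default 0.2).
#' @param groups two group labels (default c("ICM", "TE")).
#' @param seed integer seed.
#' @return object of class `sim_ct`: `ct` (sample, group, replicate,
#'   gene, ct), `true_fold` (named), `seed`.
#' @export
simulate_ct <- function(n_per_group = 6L, targets, refs,
                        true_fold = 2, noise_sd = 0.2,
                        groups = c("ICM", "TE"), seed = 1L) {
  if (!length(targets)) stop("at least one target gene is required")
  if (!length(refs)) stop("at least one reference gene is required")
  true_fold <- setNames(rep_len(true_fold, length(targets)), targets)
  if (any(true_fold <= 0)) stop("'true_fold' must be positive")
  stopifnot_scalar_count(n_per_group, "n_per_group")
  with_seed(seed, {
    base_ct <- c(setNames(runif(length(targets), 22, 28), targets),
                 setNames(runif(length(refs), 18, 24), refs))
    rows <- list()
    for (g in seq_along(groups)) {
      for (r in seq_len(n_per_group)) {
        sample_id <- paste0(groups[g], "_", r)
        for (gene in c(targets, refs)) {
          shift <- if (gene %in% targets && g == 2L) {
            -log2(true_fold[[gene]])
          } else 0
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, group = groups[g], replicate = r,
            gene = gene,
            ct = base_ct[[gene]] + shift + rnorm(1, 0, noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(ct = do.call(rbind, rows), true_fold = true_fold,
                   groups = groups, seed = seed),
              class = "sim_ct")
  })
}
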