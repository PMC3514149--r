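# End-to-end orchestration: counts -> DE lists -> clustering -> CpG +
# TFBS + ORA -> qPCR -> report, driven by one declarative config.  Every
# stage talks to the next only through its on-disk outputs or the
# documented return values; one structured log line per stage records the
# input/output record counts.

#' Build a pipeline configuration
#'
#' Collects input paths, thresholds, window sizes and the seed.  Only
#' `counts`, `conditions` and `out_dir` are mandatory; stages whose inputs
#' are NULL are skipped.
#'
#' @param counts,conditions paths to the count matrix and sample-condition
#'   TSVs.
#' @param out_dir output directory (created if missing).
#' @param fasta,tss paths to promoter FASTA and TSS TSV (CpG and motif
#'   stages).
#' @param motifs path to a JASPAR-format motif file.
#' @param term_map path to a gene-term TSV (ORA stage).
#' @param ct path to a long-format Ct TSV (qPCR stage).
#' @param alpha,min_fold DE cut-offs (defaults 0.05 and 1.5).
#' @param cpg_gc,cpg_score CpG thresholds (defaults 0.5, 0.6).
#' @param min_rel_score motif relative-score threshold (default 0.8).
#' @param k_min,k_max,elbow_threshold SSE scan controls (3, 100, 0.03).
#' @param cpg_up,cpg_down CpG window (100/100).
#' @param tfbs_up,tfbs_down motif window (200/50).
#' @param reference_positives,reference_total optional genome-wide
#'   CpG-positive reference counts for the chi-square comparison.
#' @param qpcr_targets,qpcr_refs,qpcr_calibrator qPCR stage controls.
#' @param seed integer seed for the stochastic stages (clustering).
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(counts, conditions, out_dir,
                            fasta = NULL, tss = NULL, motifs = NULL,
                            term_map = NULL, ct = NULL,
                            alpha = 0.05, min_fold = 1.5,
                            cpg_gc = 0.5, cpg_score = 0.6,
                            min_rel_score = 0.8,
                            k_min = 3L, k_max = 100L, elbow_threshold = 0.03,
                            cpg_up = 100L, cpg_down = 100L,
                            tfbs_up = 200L, tfbs_down = 50L,
                            reference_positives = NULL,
                            reference_total = NULL,
                            qpcr_targets = NULL, qpcr_refs = NULL,
                            qpcr_calibrator = NULL, seed = 1L) {
  cfg <- list(counts = counts, conditions = conditions, out_dir = out_dir,
              fasta = fasta, tss = tss, motifs = motifs,
              term_map = term_map, ct = ct,
              alpha = alpha, min_fold = min_fold,
              cpg_gc = cpg_gc, cpg_score = cpg_score,
              min_rel_score = min_rel_score,
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              elbow_threshold = elbow_threshold,
              cpg_up = as.integer(cpg_up), cpg_down = as.integer(cpg_down),
              tfbs_up = as.integer(tfbs_up),
              tfbs_down = as.integer(tfbs_down),
              reference_positives = reference_positives,
              reference_total = reference_total,
              qpcr_targets = qpcr_targets, qpcr_refs = qpcr_refs,
              qpcr_calibrator = qpcr_calibrator,
              seed = as.integer(seed))
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must lie in [0, 1]")
  if (cfg$min_fold < 1) stop("min_fold must be >= 1")
  if (cfg$min_rel_score < 0 || cfg$min_rel_score > 1) {
    stop("min_rel_score must lie in [0, 1]")
  }
  if (cfg$k_min > cfg$k_max) stop("k_min must not exceed k_max")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline config as plain key=value text
#'
#' @param config a `pipeline_config`.
#' @param path text file path.
#' @export
write_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  kv <- vapply(names(config)[keep], function(k) {
    sprintf("%s=%s", k, paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- setNames(lapply(kv, function(x) {
    v <- strsplit(paste(x[-1L], collapse = "="), ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  }), vapply(kv, `[[`, character(1), 1L))
  do.call(pipeline_config, args)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(setNames(lapply(cols, function(cl) vector(cl, 0L)),
                         names(cols)), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: differential expression, SSE-scanned
#' k-means clustering of the significant genes, promoter CpG
#' classification and proportion comparison, PWM motif enrichment, ORA,
#' and ddCt quantification — each stage only if its inputs are configured.
#' All stage outputs are written under `config$out_dir`; a `report.json`
#' summarizes record counts per stage.  Outputs are byte-reproducible for
#' a fixed config (wall-clock timing is kept only on the returned object,
#' never serialized).
#'
#' @param config a `pipeline_config`.
#' @return object of class `run_report` (also written as report.json,
#'   minus timing).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (p in c("counts", "conditions", "fasta", "tss", "motifs",
              "term_map", "ct")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop(sprintf("input '%s' not found: %s", p, config[[p]]))
    }
  }
  report <- list(version = as.character(utils::packageVersion("blastomics")),
                 seed = config$seed)

  ## -- differential expression ------------------------------------------
  counts <- read_counts_tsv(config$counts)
  condition <- read_conditions_tsv(config$conditions)
  condition <- condition[colnames(counts)]
  if (anyNA(condition)) stop("dge: conditions missing for some samples")
  dge <- dge_test(counts, condition, alpha = config$alpha,
                  min_fold = config$min_fold)
  write_dge_tsv(dge, file.path(config$out_dir, "dge_results.tsv"))
  report$n_genes <- nrow(counts)
  report$n_significant <- sum(dge$table$significant)
  report$up_in_a <- length(dge$up_in_a)
  report$up_in_b <- length(dge$up_in_b)
  report$condition_levels <- dge$levels
  stage_log("dge", "%d genes tested, %d significant (%d up-in-%s, %d up-in-%s)",
            report$n_genes, report$n_significant,
            report$up_in_a, dge$levels[1L], report$up_in_b, dge$levels[2L])
  sig_genes <- dge$table$gene[dge$table$significant]

  ## -- clustering --------------------------------------------------------
  report$chosen_k <- NA_integer_
  report$cluster_sizes <- integer(0)
  assign_path <- file.path(config$out_dir, "clusters.tsv")
  sse_path <- file.path(config$out_dir, "sse_scan.tsv")
  if (length(sig_genes) > config$k_min) {
    prof <- cluster_profiles(counts, dge$size_factors, genes = sig_genes)
    k_max_eff <- min(config$k_max, nrow(prof))
    ks <- scan_k(prof, k_min = config$k_min, k_max = k_max_eff,
                 seed = config$seed, elbow_threshold = config$elbow_threshold)
    fit <- ks$best_fit
    write.table(data.frame(gene = names(fit$assignment),
                           cluster = unname(fit$assignment)),
                assign_path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ks$scan[, c("k", "sse")], sse_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$chosen_k <- ks$chosen_k
    report$cluster_sizes <- sort(fit$sizes)
    stage_log("clustering", "scanned k = %d..%d, chose k = %d",
              config$k_min, k_max_eff, ks$chosen_k)
  } else {
    write.table(empty_df(gene = "character", cluster = "integer"),
                assign_path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(empty_df(k = "integer", sse = "numeric"), sse_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("clustering", "skipped: %d significant genes <= k_min = %d",
              length(sig_genes), config$k_min)
  }

  ## -- promoter stages ---------------------------------------------------
  have_promoters <- !is.null(config$fasta) && !is.null(config$tss)
  if (have_promoters) {
    sequences <- read_fasta(config$fasta)
    tss <- read_tss_tsv(config$tss)
    tss <- tss[tss$chrom %in% names(sequences), , drop = FALSE]

    ## CpG classification
    cpg <- cpg_profile(sequences, tss, upstream = config$cpg_up,
                       downstream = config$cpg_down,
                       gc_threshold = config$cpg_gc,
                       score_threshold = config$cpg_score)
    write.table(cpg, file.path(config$out_dir, "cpg_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pos_a <- sum(cpg$cpg_positive[cpg$gene %in% dge$up_in_a])
    tot_a <- sum(cpg$gene %in% dge$up_in_a)
    pos_b <- sum(cpg$cpg_positive[cpg$gene %in% dge$up_in_b])
    tot_b <- sum(cpg$gene %in% dge$up_in_b)
    report$cpg_fraction_up_a <- if (tot_a) pos_a / tot_a else NA_real_
    report$cpg_fraction_up_b <- if (tot_b) pos_b / tot_b else NA_real_
    cmp <- NULL
    if (tot_a > 0 && tot_b > 0) {
      cmp <- list(a_vs_b = unclass(
        compare_proportions(c(pos_a, pos_b), c(tot_a, tot_b),
                            labels = paste0("up_in_", c("A", "B")))))
      if (!is.null(config$reference_positives) &&
          !is.null(config$reference_total)) {
        cmp$de_vs_reference <- unclass(compare_proportions(
          c(pos_a + pos_b, config$reference_positives),
          c(tot_a + tot_b, config$reference_total),
          labels = c("differential", "reference")))
      }
    }
    write_json_out(cmp %||% list(),
                   file.path(config$out_dir, "cpg_comparison.json"))
    stage_log("cpg", "%d promoters scored; positive up-A %d/%d, up-B %d/%d",
              nrow(cpg), pos_a, tot_a, pos_b, tot_b)

    ## motif enrichment
    if (!is.null(config$motifs)) {
      pfms <- read_jaspar(config$motifs)
      windows <- extract_window(tss, sequences, config$tfbs_up,
                                config$tfbs_down)
      hits <- lapply(pfms, function(p) {
        motif_hits(windows, p, min_relative_score = config$min_rel_score)
      })
      names(hits) <- vapply(pfms, `[[`, character(1), "id")
      all_sites <- do.call(rbind, lapply(names(hits), function(id) {
        s <- hits[[id]]$sites
        if (nrow(s)) cbind(motif = id, s, stringsAsFactors = FALSE) else NULL
      }))
      if (is.null(all_sites)) {
        all_sites <- empty_df(motif = "character", gene = "character",
                              offset = "integer", strand = "character",
                              score = "numeric", relative_score = "numeric")
      }
      write.table(all_sites, file.path(config$out_dir, "motif_hits.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      universe <- tss$gene
      gene_sets <- lapply(hits, `[[`, "genes")
      enr_a <- enrich_motifs(intersect(dge$up_in_a, universe), universe,
                             gene_sets)
      enr_b <- enrich_motifs(intersect(dge$up_in_b, universe), universe,
                             gene_sets)
      write.table(enr_a, file.path(config$out_dir, "motif_enrichment_A.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(enr_b, file.path(config$out_dir, "motif_enrichment_B.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$enriched_motifs_a <- sum(enr_a$padj < 0.05)
      report$enriched_motifs_b <- sum(enr_b$padj < 0.05)
      stage_log("motifs", "%d motifs scanned over %d promoters; enriched: %d (up-A), %d (up-B)",
                length(pfms), length(windows),
                report$enriched_motifs_a, report$enriched_motifs_b)
    }
  }

  ## -- ORA ---------------------------------------------------------------
  if (!is.null(config$term_map)) {
    tm <- read_term_map_tsv(config$term_map)
    universe <- dge$table$gene
    ora_a <- ora_enrichment(dge$up_in_a, universe, tm)
    ora_b <- ora_enrichment(dge$up_in_b, universe, tm)
    write.table(ora_a, file.path(config$out_dir, "ora_A.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ora_b, file.path(config$out_dir, "ora_B.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$enriched_terms_a <- sum(ora_a$padj < 0.05)
    report$enriched_terms_b <- sum(ora_b$padj < 0.05)
    stage_log("ora", "enriched terms: %d (up-A), %d (up-B)",
              report$enriched_terms_a, report$enriched_terms_b)
  }

  ## -- qPCR --------------------------------------------------------------
  if (!is.null(config$ct) && !is.null(config$qpcr_targets)) {
    ct <- read_ct_tsv(config$ct)
    qres <- lapply(config$qpcr_targets, function(tg) {
      ddct(ct, tg, config$qpcr_refs,
           config$qpcr_calibrator %||% ct$group[1L])
    })
    names(qres) <- config$qpcr_targets
    per <- do.call(rbind, lapply(qres, function(r) {
      cbind(gene = r$target, r$per_sample, stringsAsFactors = FALSE)
    }))
    write.table(per, file.path(config$out_dir, "ddct_per_sample.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- lapply(qres, function(r) {
      list(group_summary = r$group_summary, t_test = r$t_test)
    })
    write_json_out(summ, file.path(config$out_dir, "qpcr_summary.json"))
    report$qpcr_fold <- vapply(qres, function(r) {
      nc <- r$group_summary$group != r$calibrator
      r$group_summary$fold[nc][1L]
    }, numeric(1))
    stage_log("qpcr", "%d targets quantified", length(qres))
  }

  write_json_out(report, file.path(config$out_dir, "report.json"))
  report$timing_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  genes: %d tested, %d significant (up-in-%s %d / up-in-%s %d)\n",
              x$n_genes, x$n_significant,
              x$condition_levels[1L], x$up_in_a,
              x$condition_levels[2L], x$up_in_b))
  if (!is.na(x$chosen_k)) {
    cat(sprintf("  clustering: k = %d, sizes %s\n", x$chosen_k,
                paste(x$cluster_sizes, collapse = ", ")))
  }
  if (!is.null(x$cpg_fraction_up_a)) {
    cat(sprintf("  CpG positive: %.1f%% (up-A), %.1f%% (up-B)\n",
                100 * x$cpg_fraction_up_a, 100 * x$cpg_fraction_up_b))
  }
  if (!is.null(x$enriched_motifs_a)) {
    cat(sprintf("  enriched motifs (padj < 0.05): %d (up-A), %d (up-B)\n",
                x$enriched_motifs_a, x$enriched_motifs_b))
  }
  if (!is.null(x$qpcr_fold)) {
    cat("  qPCR folds:",
        paste(sprintf("%s = %.2f", names(x$qpcr_fold), x$qpcr_fold),
              collapse = ", "), "\n")
  }
  if (!is.null(x$timing_s)) cat(sprintf("  wall time: %.1f s\n", x$timing_s))
  invisible(x)
}

# The three demo motifs: one information-rich 12-mer to plant plus two
# decoys, written in JASPAR text by demo_pipeline().  The 97:1:1:1 column
# profile mirrors a strong JASPAR matrix; instances drawn from it carry
# ~0-2 mismatches, well above the chance score of random promoter bases.
demo_pfms <- function() {
  mk <- function(id, name, consensus, strong = 97, weak = 1) {
    ch <- strsplit(consensus, "")[[1]]
    counts <- matrix(weak, 4L, length(ch),
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(ch)) counts[ch[j], j] <- strong
    structure(list(id = id, name = name, counts = counts), class = "pfm")
  }
  list(mk("MA9001", "PLANTED1", "TGACGTCATCGA"),
       mk("MA9002", "DECOY1", "CATTGAGGCATT"),
       mk("MA9003", "DECOY2", "GTCCATATACGG"))
}

#' One-command synthetic demonstration run
#'
#' Generates every pipeline input with [simulate_counts()],
#' [simulate_promoters()] and [simulate_ct()] (all seeds derived from
#' `seed`), writes them under `out_dir/inputs`, runs [run_pipeline()], and
#' appends planted-truth recovery metrics to the report: sensitivity on
#' strong planted genes (|log2FC| >= 2, base mean >= 100), the realized
#' false-discovery proportion, and the adjusted P of the planted motif in
#' the matching up-regulated set.
#'
#' @param seed integer master seed (default 42).
#' @param out_dir output directory (default: fresh tempdir subdirectory).
#' @param n_genes simulated genes (default 1500).
#' @param n_promoters promoter contigs simulated, covering at least all
#'   significant genes (default 1000).
#' @return the `run_report`, with elements `recovery` and
#'   `planted_motif_padj` added (also serialized into report.json).
#' @export
demo_pipeline <- function(seed = 42L, out_dir = tempfile("blastomics_demo"),
                          n_genes = 1500L, n_promoters = 1000L) {
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_counts(n_genes, seed = seed + 1L)
  write_counts_tsv(sim$counts, file.path(in_dir, "counts.tsv"))
  write_conditions_tsv(sim$condition, file.path(in_dir, "conditions.tsv"))
  write.table(sim$truth, file.path(in_dir, "truth_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # promoters for the most expressed genes (deterministic choice) so that
  # significant genes have promoters
  ord <- order(-sim$truth$base_mean * (1 + sim$truth$is_de * 10))
  prom_genes <- sort(sim$truth$gene[ord][seq_len(min(n_promoters, n_genes))])
  pfms <- demo_pfms()
  write_jaspar(pfms, file.path(in_dir, "motifs.jaspar"))
  up_a_truth <- sim$truth$gene[sim$truth$log2fc <= -1]   # up in condition A
  pool <- intersect(prom_genes, up_a_truth)
  prom <- simulate_promoters(length(prom_genes), flank = 300L,
                             gc_background = 0.4, island_fraction = 0.3,
                             motif_models = pfms[1L],
                             planted_per_motif = min(40L, length(pool)),
                             motif_genes = pool, gene_ids = prom_genes,
                             seed = seed + 2L)
  write_fasta(prom$sequences, file.path(in_dir, "promoters.fa"))
  write_tss_tsv(prom$tss, file.path(in_dir, "tss.tsv"))
  write.table(prom$motifs, file.path(in_dir, "truth_motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # term map: one term loaded with truly up-in-B genes plus random terms
  up_b_truth <- sim$truth$gene[sim$truth$log2fc >= 1]
  tm <- with_seed(seed + 3L, {
    rbind(data.frame(gene = utils::head(up_b_truth, 40L), term = "TERM_PLANTED"),
          data.frame(gene = sample(sim$truth$gene, 200L), term = "TERM_RAND1"),
          data.frame(gene = sample(sim$truth$gene, 120L), term = "TERM_RAND2"))
  })
  write.table(tm, file.path(in_dir, "term_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ct <- simulate_ct(n_per_group = 6L, targets = c("TGT1", "TGT2"),
                    refs = c("REF1", "REF2", "REF3"),
                    true_fold = c(4, 0.25), noise_sd = 0.2,
                    seed = seed + 4L)
  write_ct_tsv(ct$ct, file.path(in_dir, "ct.tsv"))

  cfg <- pipeline_config(
    counts = file.path(in_dir, "counts.tsv"),
    conditions = file.path(in_dir, "conditions.tsv"),
    out_dir = out_dir,
    fasta = file.path(in_dir, "promoters.fa"),
    tss = file.path(in_dir, "tss.tsv"),
    motifs = file.path(in_dir, "motifs.jaspar"),
    term_map = file.path(in_dir, "term_map.tsv"),
    ct = file.path(in_dir, "ct.tsv"),
    qpcr_targets = c("TGT1", "TGT2"),
    qpcr_refs = c("REF1", "REF2", "REF3"),
    qpcr_calibrator = "ICM", seed = seed)
  report <- run_pipeline(cfg)

  ## recovery metrics against the planted truth
  dge_tab <- read.delim(file.path(out_dir, "dge_results.tsv"),
                        stringsAsFactors = FALSE)
  truth <- sim$truth
  strong <- truth$gene[abs(truth$log2fc) >= 2 & truth$base_mean >= 100]
  called <- dge_tab$gene[dge_tab$significant]
  sens <- if (length(strong)) {
    length(intersect(called, strong)) / length(strong)
  } else NA_real_
  fdp <- if (length(called)) {
    length(setdiff(called, truth$gene[truth$is_de])) / length(called)
  } else 0
  enr_a <- read.delim(file.path(out_dir, "motif_enrichment_A.tsv"),
                      stringsAsFactors = FALSE)
  planted_padj <- enr_a$padj[enr_a$id == "MA9001"]
  report$recovery <- list(n_strong_planted = length(strong),
                          sensitivity = sens, fdp = fdp)
  report$planted_motif_padj <- planted_padj
  json <- jsonlite::read_json(file.path(out_dir, "report.json"))
  json$recovery <- report$recovery
  json$planted_motif_padj <- planted_padj
  write_json_out(json, file.path(out_dir, "report.json"))
  report
}
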