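# Strand-aware TSS-window extraction, GC content and CpG observed/expected
# scoring, CpG-island classification, and chi-square proportion comparison.
#
# Coordinates are 0-based half-open throughout; the TSS base itself is the
# first "downstream" base.

#' Extract strand-aware TSS windows
#'
#' For a + strand gene the window is the half-open interval
#' `[tss - upstream, tss + downstream)`.  For a - strand gene the mirrored
#' interval `[tss - downstream + 1, tss + upstream + 1)` is taken and
#' reverse-complemented, so "upstream" is always 5' of the TSS in gene
#' orientation and the returned string reads 5'->3' on the gene strand.
#'
#' @param tss data.frame with columns gene, chrom, tss (0-based), strand.
#' @param sequences named character vector (or `DNAStringSet`) of
#'   chromosome/contig sequences.
#' @param upstream,downstream window extent in bases.
#' @param clip if FALSE (default), a window extending past a sequence end
#'   is an error; if TRUE it is truncated with a warning.
#' @return named character vector of windows (names = gene ids).
#' @export
extract_window <- function(tss, sequences, upstream, downstream,
                           clip = FALSE) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  out <- character(nrow(tss))
  names(out) <- tss$gene
  for (i in seq_len(nrow(tss))) {
    chrom <- tss$chrom[i]
    if (!chrom %in% names(sequences)) {
      stop(sprintf("sequence '%s' (gene %s) not found", chrom, tss$gene[i]))
    }
    s <- sequences[[chrom]]
    L <- nchar(s)
    pos <- tss$tss[i]
    if (tss$strand[i] == "+") {
      s0 <- pos - upstream
      e0 <- pos + downstream
    } else {
      s0 <- pos - downstream + 1L
      e0 <- pos + upstream + 1L
    }
    if (s0 < 0L || e0 > L) {
      if (!clip) {
        stop(sprintf("window [%d, %d) for gene %s extends past sequence '%s' (length %d); use clip = TRUE to truncate",
                     s0, e0, tss$gene[i], chrom, L))
      }
      warning(sprintf("clipping window for gene %s to sequence bounds",
                      tss$gene[i]))
      s0 <- max(s0, 0L)
      e0 <- min(e0, L)
    }
    w <- substr(s, s0 + 1L, e0)
    if (tss$strand[i] == "-") w <- revcomp(w)
    out[i] <- w
  }
  out
}

#' GC content of a window
#'
#' `(#C + #G) / L` with L the full window length; ambiguous bases (N) count
#' zero toward the numerator but stay in the denominator.
#'
#' @param windows character vector of DNA windows.
#' @return numeric vector of proportions in \[0, 1\].
#' @export
gc_content <- function(windows) {
  if (any(!nzchar(windows))) stop("empty sequence")
  vapply(windows, function(w) {
    ch <- strsplit(toupper(w), "", fixed = TRUE)[[1]]
    sum(ch == "C" | ch == "G") / length(ch)
  }, numeric(1), USE.NAMES = !is.null(names(windows)))
}

#' CpG observed/expected score
#'
#' The Gardiner-Garden & Frommer ratio `[CG] * L / (#C * #G)`, with `[CG]`
#' the number of positions i where window\[i\] = C and window\[i+1\] = G, and
#' L the window length.  Defined 0 when #C or #G is 0.  With
#' `literal = TRUE` the formula `[CG] / (#C * #G * L)` is computed instead
#' (bounded above by 1/L; provided for fidelity testing only).
#'
#' @param windows character vector of DNA windows (length >= 2 each).
#' @param literal use the literal `[CG]/(#C * #G * L)` form (default FALSE).
#' @return numeric vector of non-negative scores.
#' @export
cpg_score <- function(windows, literal = FALSE) {
  vapply(windows, function(w) {
    L <- nchar(w)
    if (L < 2L) stop("window must have length >= 2")
    w <- toupper(w)
    ch <- strsplit(w, "", fixed = TRUE)[[1]]
    nc <- sum(ch == "C")
    ng <- sum(ch == "G")
    if (nc == 0L || ng == 0L) return(0)
    hits <- gregexpr("CG", w, fixed = TRUE)[[1]]
    ncg <- if (hits[1L] == -1L) 0L else length(hits)
    if (literal) ncg / (nc * ng * L) else ncg * L / (nc * ng)
  }, numeric(1), USE.NAMES = !is.null(names(windows)))
}

#' CpG-island classification
#'
#' Positive iff GC content strictly exceeds `gc_threshold` and the CpG
#' observed/expected score strictly exceeds `score_threshold`.
#'
#' @param gc GC content(s).
#' @param score CpG score(s).
#' @param gc_threshold default 0.5.
#' @param score_threshold default 0.6.
#' @return logical vector.
#' @export
classify_cpg <- function(gc, score, gc_threshold = 0.5,
                         score_threshold = 0.6) {
  gc > gc_threshold & score > score_threshold
}

#' Per-gene promoter CpG profile
#'
#' Extracts the TSS window (default 100 up / 100 down) for every gene and
#' computes GC content, CpG score and the island call.
#'
#' @param sequences named character vector of sequences.
#' @param tss TSS table (gene, chrom, tss, strand).
#' @param upstream,downstream window extent (defaults 100/100).
#' @inheritParams classify_cpg
#' @inheritParams extract_window
#' @return data.frame: gene, gc_content, cpg_score, cpg_positive.
#' @export
cpg_profile <- function(sequences, tss, upstream = 100L, downstream = 100L,
                        gc_threshold = 0.5, score_threshold = 0.6,
                        clip = FALSE) {
  w <- extract_window(tss, sequences, upstream, downstream, clip = clip)
  gc <- gc_content(w)
  sc <- cpg_score(w)
  data.frame(gene = tss$gene, gc_content = unname(gc),
             cpg_score = unname(sc),
             cpg_positive = unname(classify_cpg(gc, sc, gc_threshold,
                                                score_threshold)),
             stringsAsFactors = FALSE)
}

#' Chi-square comparison of CpG-positive proportions
#'
#' Pearson chi-square (no continuity correction) on the groups x
#' (positive, negative) contingency table.
#'
#' @param positives integer vector of positive counts per group.
#' @param totals integer vector of group totals (> 0).
#' @param labels group labels (defaults to names of `positives`).
#' @return object of class `prop_comparison`: labels, positives, totals,
#'   statistic, df, p.value.
#' @export
compare_proportions <- function(positives, totals,
                                labels = names(positives)) {
  if (length(positives) != length(totals)) {
    stop("positives and totals must have equal length")
  }
  if (any(totals <= 0)) stop("all totals must be positive")
  if (any(positives < 0 | positives > totals)) {
    stop("positives must lie in [0, total] for every group")
  }
  labels <- labels %||% paste0("group", seq_along(positives))
  tab <- cbind(positive = positives, negative = totals - positives)
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cells < 1)) {
    warning("expected cell count below 1; chi-square approximation is poor")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(labels = labels,
                 positives = positives, totals = totals,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value),
            class = "prop_comparison")
}

#' @export
print.prop_comparison <- function(x, ...) {
  cat("Chi-square comparison of proportions\n")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %s: %d / %d (%.1f%%)\n", x$labels[i], x$positives[i],
                x$totals[i], 100 * x$positives[i] / x$totals[i]))
  }
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}
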