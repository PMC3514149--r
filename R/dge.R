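# Two-condition negative-binomial differential expression.
#
# The pipeline: median-of-ratios size factors -> pooled method-of-moments
# variance with a locally regressed mean-variance trend -> exact conditional
# test on the split of the per-condition count sums -> Benjamini-Hochberg
# adjustment -> dual cut-off calling (adjusted P and minimum fold change).

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes (restricted to genes with positive
#' counts in every sample) of the ratio of the count to the gene's
#' geometric mean across samples, rescaled so the size factors have
#' geometric mean 1.
#'
#' @param counts non-negative integer matrix, genes in rows.
#' @return named numeric vector of positive size factors (geometric mean 1).
#' @export
#' @examples
#' m <- matrix(rpois(60, 50), nrow = 10)
#' estimate_size_factors(m + 1L)
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  logg <- rowMeans(log(counts))
  ok <- is.finite(logg)           # rows positive in every sample
  if (!any(ok)) {
    stop("no gene has positive counts in every sample; size factors are ",
         "unidentifiable with the median-of-ratios estimator. Filter to a ",
         "subset of samples in which some genes are always detected.")
  }
  sf <- apply(counts, 2L, function(col) {
    exp(median(log(col[ok]) - logg[ok]))
  })
  sf <- sf / exp(mean(log(sf)))   # geometric mean exactly 1
  names(sf) <- colnames(counts)
  sf
}

#' Fit the mean-variance trend of normalized counts
#'
#' Per gene, the within-condition sample variance of normalized counts is
#' pooled across the two conditions (degrees-of-freedom weighted) and
#' regressed on the overall normalized mean by loess on the log-log scale
#' (tricube weights).  The back-transformed fit receives the analytic
#' chi-square log-bias correction `exp(log(df/2) - digamma(df/2))`, is made
#' monotone non-decreasing by a running maximum over a log-spaced grid, and
#' is floored at the mean (Poisson floor).
#'
#' @param counts non-negative integer matrix, genes in rows.
#' @param sf size factors as from [estimate_size_factors()].
#' @param condition factor of length `ncol(counts)` with exactly two levels
#'   and at least two replicates each.
#' @param span loess span (default 0.3).
#' @return an object of class `dispersion_fit`: the per-gene table, the
#'   monotone fitted variance function, and the pooled degrees of freedom.
#' @export
fit_dispersion <- function(counts, sf, condition, span = 0.3) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions are required")
  reps <- table(condition)
  if (any(reps < 2L)) stop("at least 2 replicates per condition are required")
  ncts <- sweep(counts, 2L, sf, "/")
  lv <- levels(condition)
  m_all <- rowMeans(ncts)
  v_pool <- rep(0, nrow(ncts))
  df_pool <- 0L
  for (l in lv) {
    sub <- ncts[, condition == l, drop = FALSE]
    d <- ncol(sub) - 1L
    v_pool <- v_pool + d * apply(sub, 1L, var)
    df_pool <- df_pool + d
  }
  v_pool <- v_pool / df_pool

  pos <- m_all > 0
  if (sum(pos) < 10L) {
    stop("fewer than 10 genes with positive mean; mean-variance fit is ",
         "unidentifiable")
  }
  fit_idx <- pos & v_pool > 0
  if (sum(fit_idx) < 10L) {
    # no usable variance signal (e.g. replicate-constant counts): the fit
    # degenerates to the Poisson floor, variance(m) = m
    return(structure(list(
      table = data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
                         mean = m_all, raw_variance = v_pool,
                         stringsAsFactors = FALSE),
      fitted_var = function(m) m,
      df = df_pool, span = span, bias_correction = 1,
      floor = "variance >= mean", mean_range = range(m_all[pos])
    ), class = "dispersion_fit"))
  }
  lo <- loess(logv ~ logm,
              data = data.frame(logm = log(m_all[fit_idx]),
                                logv = log(v_pool[fit_idx])),
              span = span, degree = 1, family = "gaussian",
              control = loess.control(surface = "direct"))
  # E[log v_hat] = log v + digamma(df/2) - log(df/2) for chi-square v_hat
  bias_corr <- exp(log(df_pool / 2) - digamma(df_pool / 2))

  rng <- range(log(m_all[fit_idx]))
  grid <- seq(rng[1L], rng[2L], length.out = 200L)
  vg <- exp(predict(lo, data.frame(logm = grid))) * bias_corr
  vg <- cummax(vg)                              # monotone non-decreasing
  vfun_raw <- approxfun(grid, vg, rule = 2L)    # clamp outside fitted range

  fitted_var <- function(m) {
    v <- vfun_raw(log(pmax(m, exp(rng[1L]))))
    pmax(v, m)                                  # Poisson floor
  }

  structure(list(
    table = data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
                       mean = m_all, raw_variance = v_pool,
                       stringsAsFactors = FALSE),
    fitted_var = fitted_var,
    df = df_pool,
    span = span,
    bias_correction = bias_corr,
    floor = "variance >= mean",
    mean_range = exp(rng)
  ), class = "dispersion_fit")
}

#' @rdname fit_dispersion
#' @param object a `dispersion_fit`.
#' @param mean normalized mean(s) at which to evaluate the fit.
#' @param ... ignored.
#' @return `predict()`: fitted variance at `mean`, always `>= mean`.
#' @export
predict.dispersion_fit <- function(object, mean, ...) {
  object$fitted_var(mean)
}

#' Dispersion implied by the fitted trend
#'
#' `d(m) = (v(m) - m) / m^2`, the NB overdispersion in
#' `variance = mean + d * mean^2`.
#'
#' @param fit a `dispersion_fit`.
#' @param mean normalized mean(s).
#' @return non-negative dispersion value(s).
#' @export
dispersion_at <- function(fit, mean) {
  (predict(fit, mean) - mean) / mean^2
}

# log NB (or Poisson when variance <= mean) mass with mean/variance
# parameterization.
dnb_log <- function(x, mu, v) {
  if (mu <= 0) return(ifelse(x == 0, 0, -Inf))
  if (v <= mu * (1 + 1e-8)) {
    dpois(x, lambda = mu, log = TRUE)
  } else {
    dnbinom(x, mu = mu, size = mu^2 / (v - mu), log = TRUE)
  }
}

#' Exact conditional NB test for one gene
#'
#' Conditions on the observed total `K = K_A + K_B` of the per-condition
#' count sums and enumerates every split `(a, K - a)`.  Under the null of a
#' common expression level, each condition sum is NB with mean
#' `q0 * sum(sf)` and variance `q0 * sum(sf) + (v(q0) - q0) * sum(sf^2)`,
#' where `q0` is the pooled normalized mean and `v()` the fitted
#' mean-variance trend.  The p-value is the total probability of splits no
#' more likely than the observed one, normalized over all splits.
#'
#' @param counts_a,counts_b integer count vectors for the two conditions.
#' @param sf_a,sf_b size factors for the corresponding samples.
#' @param fit a `dispersion_fit` (or a plain function mapping mean to
#'   variance on the normalized scale).
#' @return p-value in (0, 1]; total count 0 returns 1 by convention.
#' @export
nb_test <- function(counts_a, counts_b, sf_a, sf_b, fit) {
  ka <- sum(counts_a)
  kb <- sum(counts_b)
  K <- ka + kb
  if (K == 0) return(1)
  vfun <- if (inherits(fit, "dispersion_fit")) fit$fitted_var else fit
  q0 <- K / (sum(sf_a) + sum(sf_b))
  v0 <- vfun(q0)
  extra <- max(v0 - q0, 0)
  mu_a <- q0 * sum(sf_a)
  mu_b <- q0 * sum(sf_b)
  var_a <- mu_a + extra * sum(sf_a^2)
  var_b <- mu_b + extra * sum(sf_b^2)

  a <- 0:K
  lp <- dnb_log(a, mu_a, var_a) + dnb_log(K - a, mu_b, var_b)
  lobs <- lp[ka + 1L]
  denom <- logsumexp(lp)
  if (!is.finite(denom)) return(1)
  keep <- lp <= lobs + 1e-8     # tie tolerance for equal-probability splits
  p <- exp(logsumexp(lp[keep]) - denom)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; order-preserving and never below the raw value.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Fold change between normalized condition means
#'
#' Returns `mean_b / mean_a`.  `mean_a = 0` with `mean_b > 0` yields `Inf`;
#' both zero yields `NA` (undefined).
#'
#' @param mean_a,mean_b non-negative normalized condition means.
#' @return numeric vector of ratios.
#' @export
#' @examples
#' fold_change(363.6, 976.7)  # 2.69 at 2 decimals
fold_change <- function(mean_a, mean_b) {
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE)) {
    stop("means must be non-negative")
  }
  fc <- mean_b / mean_a
  fc[mean_a == 0 & mean_b == 0] <- NA_real_
  fc
}

#' Dual cut-off significance calling
#'
#' A gene is significant iff `padj <= alpha` and
#' `max(fold, 1/fold) >= min_fold` (the fold gate is symmetric).  Direction
#' is up-in-B for fold > 1, up-in-A for fold < 1.
#'
#' @param records data.frame with columns `gene`, `fold_change`, `padj`.
#' @param alpha adjusted-P threshold (default 0.05).
#' @param min_fold minimum fold change (default 1.5).
#' @return list with the augmented `table` (columns `significant`,
#'   `direction`) and the partitioned gene id vectors `up_in_a`, `up_in_b`.
#' @export
call_de <- function(records, alpha = 0.05, min_fold = 1.5) {
  fc <- records$fold_change
  sym <- pmax(fc, 1 / fc)                    # Inf-safe; NA stays NA
  sig <- !is.na(records$padj) & records$padj <= alpha &
    !is.na(sym) & sym >= min_fold
  dir <- rep("none", nrow(records))
  dir[sig & fc > 1] <- "up-in-B"
  dir[sig & fc < 1] <- "up-in-A"
  records$significant <- sig
  records$direction <- dir
  list(table = records,
       up_in_a = records$gene[dir == "up-in-A"],
       up_in_b = records$gene[dir == "up-in-B"])
}

#' Two-condition differential expression analysis
#'
#' Runs the full stack: size factors, mean-variance trend, per-gene exact
#' conditional NB test, BH adjustment and dual cut-off calling.  Condition
#' A is the first factor level, condition B the second; fold changes are
#' B/A.
#'
#' @param counts non-negative integer matrix, genes in rows.
#' @param condition factor (or coercible) of length `ncol(counts)` with two
#'   levels, >= 2 replicates each.
#' @param alpha adjusted-P cut-off (default 0.05).
#' @param min_fold minimum fold-change cut-off (default 1.5).
#' @param sf,fit optional precomputed size factors / dispersion fit.
#' @return object of class `dge_result` with elements `table` (gene,
#'   mean_A, mean_B, fold_change, pvalue, padj, significant, direction),
#'   `up_in_a`, `up_in_b`, `size_factors`, `dispersion_fit`, `levels`,
#'   `alpha`, `min_fold`.
#' @export
dge_test <- function(counts, condition, alpha = 0.05, min_fold = 1.5,
                     sf = NULL, fit = NULL) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions are required")
  if (length(condition) != ncol(counts)) {
    stop("length(condition) must equal ncol(counts)")
  }
  if (is.null(sf)) sf <- estimate_size_factors(counts)
  if (is.null(fit)) fit <- fit_dispersion(counts, sf, condition)
  lv <- levels(condition)
  ia <- condition == lv[1L]
  ib <- condition == lv[2L]
  ncts <- sweep(counts, 2L, sf, "/")
  mean_a <- rowMeans(ncts[, ia, drop = FALSE])
  mean_b <- rowMeans(ncts[, ib, drop = FALSE])
  pv <- vapply(seq_len(nrow(counts)), function(i) {
    nb_test(counts[i, ia], counts[i, ib], sf[ia], sf[ib], fit)
  }, numeric(1))
  tab <- data.frame(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_A = mean_a, mean_B = mean_b,
    fold_change = fold_change(mean_a, mean_b),
    pvalue = pv, padj = adjust_bh(pv),
    stringsAsFactors = FALSE, row.names = NULL
  )
  called <- call_de(tab, alpha = alpha, min_fold = min_fold)
  structure(list(table = called$table,
                 up_in_a = called$up_in_a, up_in_b = called$up_in_b,
                 size_factors = sf, dispersion_fit = fit,
                 levels = lv, alpha = alpha, min_fold = min_fold),
            class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  cat("Negative-binomial differential expression (exact conditional test)\n")
  cat(sprintf("  conditions: A = %s, B = %s (fold change = B/A)\n",
              x$levels[1L], x$levels[2L]))
  cat(sprintf("  genes tested: %d\n", nrow(x$table)))
  cat(sprintf("  significant (padj <= %g, fold >= %g): %d  [up-in-%s: %d, up-in-%s: %d]\n",
              x$alpha, x$min_fold, sum(x$table$significant),
              x$levels[1L], length(x$up_in_a),
              x$levels[2L], length(x$up_in_b)))
  invisible(x)
}

#' @export
summary.dge_result <- function(object, n = 10L, ...) {
  print(object)
  tab <- object$table[order(object$table$padj), ]
  cat("\nTop genes by adjusted P:\n")
  print(head(tab, n), digits = 4)
  invisible(tab)
}

#' Write a differential-expression results table to TSV
#'
#' @param x a `dge_result` or its `table`.
#' @param path output TSV path.
#' @export
write_dge_tsv <- function(x, path) {
  tab <- if (inherits(x, "dge_result")) x$table else x
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
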