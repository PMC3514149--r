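# Delta-delta-Ct relative quantification against a multi-gene reference.

#' Per-sample reference Ct
#'
#' Combines the reference-gene Ct values of one sample.  The default
#' (`mode = "mean_ct"`) takes the arithmetic mean of the Ct values — the
#' geometric mean of the corresponding expression levels, since Ct values
#' are exponents — which is the standard multi-reference normalization.
#' `mode = "geometric_ct"` instead takes the literal geometric mean of the
#' Ct numbers.
#'
#' @param ct_values numeric vector of reference Ct values (one sample).
#' @param mode "mean_ct" (default) or "geometric_ct".
#' @return reference Ct scalar.
#' @export
#' @examples
#' reference_ct(c(18, 22))                      # 20
#' reference_ct(c(18, 22), "geometric_ct")      # 19.90
reference_ct <- function(ct_values, mode = c("mean_ct", "geometric_ct")) {
  mode <- match.arg(mode)
  if (!length(ct_values)) stop("at least one reference gene is required")
  if (anyNA(ct_values)) stop("missing reference Ct value")
  if (any(ct_values <= 0)) stop("Ct values must be positive")
  switch(mode,
         mean_ct = mean(ct_values),
         geometric_ct = exp(mean(log(ct_values))))
}

#' Delta-delta-Ct quantification for one target gene
#'
#' Per sample: `dCt = Ct_target - referenceCt`;
#' `ddCt = dCt - mean(dCt over the calibrator group)`;
#' `fold = 2^(-ddCt)` (amplification efficiency fixed at 2).  Group mean
#' folds are reported both as `2^(-mean ddCt)` and as the arithmetic mean
#' of per-sample folds, plus a Welch t-test on ddCt between the two
#' groups.
#'
#' @param ct long-format data.frame with columns sample, group, gene, ct.
#' @param target target gene id.
#' @param refs character vector of reference gene ids.
#' @param calibrator group label used as calibrator (its mean ddCt is 0 by
#'   construction).
#' @param ref_mode passed to [reference_ct()].
#' @return object of class `ddct_result`: `per_sample` (sample, group,
#'   dct, ddct, fold), `group_summary` (group, n, mean_ddct, fold,
#'   mean_fold), `t_test` (statistic, df, p.value), plus target/refs/
#'   calibrator.
#' @export
ddct <- function(ct, target, refs, calibrator,
                 ref_mode = c("mean_ct", "geometric_ct")) {
  ref_mode <- match.arg(ref_mode)
  if (!length(refs)) stop("at least one reference gene is required")
  samples <- unique(ct$sample)
  groups <- setNames(ct$group[match(samples, ct$sample)], samples)
  if (!calibrator %in% groups) {
    stop(sprintf("calibrator group '%s' has no samples", calibrator))
  }
  dct <- vapply(samples, function(s) {
    sub <- ct[ct$sample == s, ]
    tct <- sub$ct[sub$gene == target]
    if (length(tct) != 1L) {
      stop(sprintf("target '%s' not measured exactly once in sample '%s'",
                   target, s))
    }
    rct <- vapply(refs, function(r) {
      v <- sub$ct[sub$gene == r]
      if (length(v) != 1L) {
        stop(sprintf("reference '%s' not measured exactly once in sample '%s'",
                     r, s))
      }
      v
    }, numeric(1))
    tct - reference_ct(rct, ref_mode)
  }, numeric(1))
  ddct_v <- dct - mean(dct[groups == calibrator])
  fold <- 2^(-ddct_v)
  per_sample <- data.frame(sample = samples, group = unname(groups),
                           dct = unname(dct), ddct = unname(ddct_v),
                           fold = unname(fold), stringsAsFactors = FALSE)
  gl <- unique(per_sample$group)
  group_summary <- do.call(rbind, lapply(gl, function(g) {
    d <- per_sample$ddct[per_sample$group == g]
    data.frame(group = g, n = length(d), mean_ddct = mean(d),
               fold = 2^(-mean(d)),
               mean_fold = mean(2^(-d)), stringsAsFactors = FALSE)
  }))
  t_test <- NULL
  if (length(gl) == 2L) {
    t_test <- tryCatch({
      ht <- t.test(per_sample$ddct[per_sample$group == gl[1L]],
                   per_sample$ddct[per_sample$group == gl[2L]])
      list(statistic = unname(ht$statistic),
           df = unname(ht$parameter), p.value = ht$p.value)
    }, error = function(e) {
      # noise-free fixtures have zero within-group variance
      list(statistic = NA_real_, df = NA_real_, p.value = NA_real_)
    })
  }
  structure(list(target = target, refs = refs, calibrator = calibrator,
                 ref_mode = ref_mode, per_sample = per_sample,
                 group_summary = group_summary, t_test = t_test),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddCt quantification of %s (refs: %s; calibrator: %s)\n",
              x$target, paste(x$refs, collapse = ", "), x$calibrator))
  print(x$group_summary, digits = 4, row.names = FALSE)
  if (!is.null(x$t_test)) {
    cat(sprintf("Welch t-test on ddCt: t = %.3f, df = %.2f, p = %.4g\n",
                x$t_test$statistic, x$t_test$df, x$t_test$p.value))
  }
  invisible(x)
}
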