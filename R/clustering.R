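# k-means clustering of expression profiles with an SSE scan over k.
#
# Lloyd's algorithm with k-means++ initialization, best-of-restarts under a
# single seed, and a warm-start policy over the k scan that guarantees the
# best SSE is non-increasing in k.

# Squared Euclidean distances between every row of x and every row of
# centers: n x k matrix.
dist2_matrix <- function(x, centers) {
  n2x <- rowSums(x^2)
  n2c <- rowSums(centers^2)
  d2 <- outer(n2x, n2c, "+") - 2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

# k-means++ seeding: first center uniform, then each subsequent center
# drawn with probability proportional to squared distance to the nearest
# chosen center.  Uses the current RNG stream.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- dist2_matrix(x, x[idx[1L], , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      cand <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- if (length(cand)) cand[1L] else sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, dist2_matrix(x, x[idx[j], , drop = FALSE])[, 1L])
  }
  x[idx, , drop = FALSE]
}

# Lloyd iterations from given centers; deterministic (ties go to the
# lowest-index centroid).  Empty clusters are reseeded with the point
# currently farthest from its assigned centroid.
lloyd <- function(x, centers, iter_max = 100L) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_prev <- integer(n)
  for (it in seq_len(iter_max)) {
    d2 <- dist2_matrix(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    point_d2 <- d2[cbind(seq_len(n), assign)]
    for (j in which(tabulate(assign, k) == 0L)) {
      far <- which.max(point_d2)
      assign[far] <- j
      point_d2[far] <- 0
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    sums <- rowsum(x, assign, reorder = FALSE)
    cl <- as.integer(rownames(sums))
    centers[cl, ] <- sums / tabulate(assign, k)[cl]
  }
  d2 <- dist2_matrix(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(n), assign)])
  list(assignment = assign, centroids = centers, sse = sse)
}

#' k-means clustering of gene profiles
#'
#' Best-of-`n_restarts` Lloyd's algorithm with k-means++ initialization.
#' Deterministic for a fixed `seed`.  Cluster indices are 1..k (R
#' convention).
#'
#' @param x numeric matrix, genes in rows (no missing values).
#' @param k number of clusters, `k <= nrow(x)`.
#' @param seed integer seed controlling all restarts.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param extra_centers optional list of k x ncol center matrices used as
#'   additional warm starts (used by [scan_k()]).
#' @param iter_max Lloyd iteration cap per restart.
#' @return object of class `kmeans_result`: `k`, `assignment` (named
#'   integer vector), `centroids`, `sse`, `sizes`, `seed`, `n_restarts`.
#' @export
kmeans_fit <- function(x, k, seed = 1L, n_restarts = 10L,
                       extra_centers = NULL, iter_max = 100L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not allowed")
  stopifnot_scalar_count(k, "k")
  if (k > nrow(x)) stop("k must not exceed the number of rows")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      res <- lloyd(x, kmeanspp_init(x, k), iter_max)
      if (is.null(best) || res$sse < best$sse) best <- res
    }
  })
  for (ctr in extra_centers %||% list()) {
    res <- lloyd(x, as.matrix(ctr), iter_max)
    if (is.null(best) || res$sse < best$sse) best <- res
  }
  structure(list(k = k,
                 assignment = setNames(best$assignment,
                                       rownames(x) %||% seq_len(nrow(x))),
                 centroids = best$centroids,
                 sse = best$sse,
                 sizes = tabulate(best$assignment, k),
                 seed = seed, n_restarts = n_restarts),
            class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("k-means: k = %d, n = %d, SSE = %.4g\n",
              x$k, length(x$assignment), x$sse))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' SSE scan over k with elbow selection
#'
#' Runs [kmeans_fit()] for each k in `[k_min, k_max]`.  Each k receives,
#' besides its k-means++ restarts, one warm start built from the previous
#' k's best solution with its widest cluster split (new centroid at the
#' point farthest from that cluster's centroid); since Lloyd never
#' increases the SSE of its starting configuration, the best SSE is
#' non-increasing in k.  The chosen k is the smallest k whose relative SSE
#' drop to k+1, `(sse(k) - sse(k+1)) / sse(k)`, falls below
#' `elbow_threshold` (0/0 counts as 0); if none does, `k_max`.
#'
#' @param x numeric matrix, genes in rows.
#' @param k_min,k_max scan range (defaults 3 and 100); `k_max <= nrow(x)`.
#' @param seed integer seed.
#' @param n_restarts restarts per k (default 10).
#' @param elbow_threshold relative-drop threshold (default 0.03).
#' @return object of class `kscan`: data.frame `scan` (k, sse), `chosen_k`,
#'   `fits` is not retained except the fit at `chosen_k` (`best_fit`).
#' @export
scan_k <- function(x, k_min = 3L, k_max = 100L, seed = 1L, n_restarts = 10L,
                   elbow_threshold = 0.03) {
  x <- as.matrix(x)
  if (k_min > k_max) stop("k_min must not exceed k_max")
  if (k_max > nrow(x)) stop("k_max must not exceed the number of rows")
  ks <- k_min:k_max
  sses <- numeric(length(ks))
  fits <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    extra <- NULL
    if (!is.null(prev)) {
      # split the cluster with the largest within-cluster SSE
      d2 <- dist2_matrix(x, prev$centroids)
      pd <- d2[cbind(seq_len(nrow(x)), prev$assignment)]
      wsse <- vapply(seq_len(prev$k),
                     function(j) sum(pd[prev$assignment == j]), numeric(1))
      widest <- which.max(wsse)
      in_w <- which(prev$assignment == widest)
      far <- in_w[which.max(pd[in_w])]
      extra <- list(rbind(prev$centroids, x[far, , drop = FALSE]))
    }
    fits[[i]] <- kmeans_fit(x, k, seed = seed + k, n_restarts = n_restarts,
                            extra_centers = extra)
    sses[i] <- fits[[i]]$sse
    prev <- fits[[i]]
  }
  drop_rel <- rep(NA_real_, length(ks))
  if (length(ks) > 1L) {
    num <- sses[-length(sses)] - sses[-1L]
    den <- sses[-length(sses)]
    dr <- ifelse(den > 0, num / den, 0)
    drop_rel[seq_len(length(ks) - 1L)] <- dr
    below <- which(dr < elbow_threshold)
    chosen <- if (length(below)) ks[below[1L]] else k_max
  } else {
    chosen <- k_min
  }
  structure(list(scan = data.frame(k = ks, sse = sses,
                                   rel_drop = drop_rel),
                 chosen_k = chosen,
                 best_fit = fits[[match(chosen, ks)]],
                 elbow_threshold = elbow_threshold,
                 seed = seed, n_restarts = n_restarts),
            class = "kscan")
}

#' @export
print.kscan <- function(x, ...) {
  cat(sprintf("SSE scan over k = %d..%d; chosen k = %d (relative-drop threshold %g)\n",
              min(x$scan$k), max(x$scan$k), x$chosen_k, x$elbow_threshold))
  invisible(x)
}

#' @rdname scan_k
#' @param ... passed to `plot()`.
#' @export
plot.kscan <- function(x, ...) {
  plot(x$scan$k, x$scan$sse, type = "b", pch = 20,
       xlab = "k", ylab = "best SSE", ...)
  abline(v = x$chosen_k, lty = 2)
  invisible(x)
}

#' Row standardization for heatmap display
#'
#' Centers every row at mean 0 and scales to unit sample standard
#' deviation (`n - 1` denominator); rows with zero variance map to all
#' zeros.
#'
#' @param x numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
standardize_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("rows need more than one column to standardize")
  ctr <- x - rowMeans(x)
  s <- apply(x, 1L, sd)
  out <- ctr / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Expression profiles for clustering
#'
#' Size-factor-normalized counts, optionally log2(x + 1) transformed
#' (default), restricted to a gene subset.
#'
#' @param counts count matrix, genes in rows.
#' @param sf size factors.
#' @param genes optional gene ids to keep.
#' @param log2 apply log2(x + 1) (default TRUE).
#' @return numeric matrix.
#' @export
cluster_profiles <- function(counts, sf, genes = NULL, log2 = TRUE) {
  ncts <- sweep(as.matrix(counts), 2L, sf, "/")
  if (!is.null(genes)) ncts <- ncts[rownames(ncts) %in% genes, , drop = FALSE]
  if (log2) base::log2(ncts + 1) else ncts
}

#' Clustered heatmap of standardized profiles
#'
#' Draws a heatmap of [standardize_rows()] output with rows ordered by
#' cluster; blue marks values below the row mean, red above.  Requires the
#' pheatmap package.
#'
#' @param profiles numeric matrix (genes x samples).
#' @param assignment named cluster assignment as from [kmeans_fit()].
#' @param filename optional PNG path; NULL draws to the active device.
#' @return invisibly, the standardized, reordered matrix.
#' @export
cluster_heatmap <- function(profiles, assignment, filename = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("cluster_heatmap() requires the 'pheatmap' package")
  }
  z <- standardize_rows(profiles)
  ord <- order(assignment[rownames(z)])
  z <- z[ord, , drop = FALSE]
  ann <- data.frame(cluster = factor(assignment[rownames(z)]))
  rownames(ann) <- rownames(z)
  pheatmap::pheatmap(z, cluster_rows = FALSE, cluster_cols = FALSE,
                     annotation_row = ann, show_rownames = FALSE,
                     filename = filename %||% NA)
  invisible(z)
}
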