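# PWM scanning of promoter windows and hypergeometric enrichment.
#
# PFMs come from JASPAR-format text; log-odds weights follow the standard
# additive-pseudocount construction, sites are scored at every offset on
# both strands, and a gene "has" a motif iff at least one site reaches the
# relative-score threshold.  The same hypergeometric machinery backs a
# generic over-representation analysis over gene -> term mappings.

#' Read motifs from JASPAR-format text
#'
#' Accepts both dialects: headers `>ID NAME`, then either four labelled
#' rows `A [ 4 19 0 ]` (brackets optional) or four bare numeric rows in
#' A, C, G, T order.
#'
#' @param path path to the motif file.
#' @return list of `pfm` objects (fields id, name, counts: 4 x L matrix
#'   with rownames A,C,G,T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    body <- lines[(starts[i] + 1L):ends[i]]
    counts <- matrix(NA_real_, 4L, 0L,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    rows <- list()
    order_fallback <- c("A", "C", "G", "T")
    for (ln in body) {
      clean <- gsub("\\[|\\]", " ", ln)
      toks <- strsplit(trimws(clean), "\\s+")[[1]]
      base <- NA_character_
      if (toupper(toks[1L]) %in% order_fallback &&
          is.na(suppressWarnings(as.numeric(toks[1L])))) {
        base <- toupper(toks[1L])
        toks <- toks[-1L]
      }
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals)) {
        stop(sprintf("motif %s: cannot parse row '%s'", id, ln))
      }
      if (is.na(base)) base <- order_fallback[length(rows) + 1L]
      rows[[base]] <- vals
    }
    if (!all(order_fallback %in% names(rows))) {
      stop(sprintf("motif %s: missing base row(s) %s", id,
                   paste(setdiff(order_fallback, names(rows)),
                         collapse = ", ")))
    }
    lens <- lengths(rows[order_fallback])
    if (length(unique(lens)) != 1L) {
      stop(sprintf("motif %s: ragged columns (row lengths %s)", id,
                   paste(lens, collapse = ", ")))
    }
    counts <- do.call(rbind, rows[order_fallback])
    rownames(counts) <- order_fallback
    if (any(counts < 0)) stop(sprintf("motif %s: negative counts", id))
    if (any(colSums(counts) <= 0)) {
      stop(sprintf("motif %s: column with no positive entry", id))
    }
    structure(list(id = id, name = name, counts = counts), class = "pfm")
  })
}

#' @rdname read_jaspar
#' @param pfms list of `pfm` objects (or a single one).
#' @export
write_jaspar <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Build a log-odds PWM from a count matrix
#'
#' `weight(b, j) = log2((count(b, j) + pc * bg(b)) / (N_j + pc) / bg(b))`
#' with `N_j` the column total, `pc` the pseudocount (distributed by
#' background frequency) and `bg` the background distribution.
#'
#' @param pfm a `pfm` object or a 4 x L count matrix (rows A,C,G,T).
#' @param pseudocount positive pseudocount total (default 0.8).
#' @param background named base frequencies summing to 1 (default uniform).
#' @return object of class `pwm_model`: weights (4 x L), probs (corrected
#'   per-column base probabilities), background, pseudocount, score_min,
#'   score_max, consensus, id, name.
#' @export
pwm_from_pfm <- function(pfm, pseudocount = 0.8,
                         background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  if (inherits(pfm, "pwm_model")) return(pfm)
  if (inherits(pfm, "pfm")) {
    counts <- pfm$counts; id <- pfm$id; name <- pfm$name
  } else {
    counts <- as.matrix(pfm); id <- "motif"; name <- "motif"
    rownames(counts) <- c("A", "C", "G", "T")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("pseudocount must be a positive scalar")
  }
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be positive frequencies over A,C,G,T summing to 1")
  }
  nj <- colSums(counts)
  probs <- sweep(counts + pseudocount * background, 2L, nj + pseudocount, "/")
  w <- log2(sweep(probs, 1L, background, "/"))
  structure(list(weights = w, probs = probs, background = background,
                 pseudocount = pseudocount,
                 score_min = sum(apply(w, 2L, min)),
                 score_max = sum(apply(w, 2L, max)),
                 consensus = paste(rownames(w)[apply(w, 2L, which.max)],
                                   collapse = ""),
                 length = ncol(w), id = id, name = name),
            class = "pwm_model")
}

# Score every offset of a coded sequence against the weight matrix; sites
# containing NA codes (N bases) score NA.
scan_codes <- function(codes, w) {
  L <- ncol(w)
  n_off <- length(codes) - L + 1L
  if (n_off < 1L) return(numeric(0))
  pos <- outer(seq_len(n_off) - 1L, seq_len(L), "+")     # n_off x L indices
  cmat <- matrix(codes[pos], n_off, L)
  lin <- cmat + 4L * rep(seq_len(L) - 1L, each = n_off)
  rowSums(matrix(w[lin], n_off, L))
}

#' Scan a promoter window with a PWM
#'
#' Scores every offset (0-based, leftmost base of the site on the given
#' window) and, when `both_strands`, every reverse-complement reading.
#' The relative score is `(score - score_min) / (score_max - score_min)`,
#' in \[0, 1\].  Sites containing N are skipped.
#'
#' @param window DNA string of length >= motif length.
#' @param pwm a `pwm_model` (or `pfm`, converted with defaults).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame: offset, strand, score, relative_score.
#' @export
scan_promoter <- function(window, pwm, both_strands = TRUE) {
  pwm <- pwm_from_pfm(pwm)
  L <- pwm$length
  W <- nchar(window)
  if (W < L) stop("window is shorter than the motif")
  codes <- dna_codes(window)
  sc_f <- scan_codes(codes, pwm$weights)
  off_f <- seq_along(sc_f) - 1L
  res <- data.frame(offset = off_f, strand = "+", score = sc_f,
                    stringsAsFactors = FALSE)
  if (both_strands) {
    sc_r <- scan_codes(rev(5L - codes), pwm$weights)   # codes of revcomp
    off_r <- W - L - (seq_along(sc_r) - 1L)
    res <- rbind(res, data.frame(offset = off_r, strand = "-", score = sc_r,
                                 stringsAsFactors = FALSE))
  }
  res <- res[!is.na(res$score), , drop = FALSE]
  denom <- pwm$score_max - pwm$score_min
  res$relative_score <- if (denom > 0) {
    (res$score - pwm$score_min) / denom
  } else {
    rep(1, nrow(res))
  }
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Threshold scanned sites
#'
#' Keeps sites whose relative score reaches `min_relative_score`.
#'
#' @param sites data.frame as from [scan_promoter()] (optionally with a
#'   `gene` column).
#' @param min_relative_score threshold in \[0, 1\] (default 0.80).
#' @return filtered data.frame.
#' @export
call_hits <- function(sites, min_relative_score = 0.80) {
  # tolerance so sites exactly at the threshold are kept despite rounding
  keep <- sites$relative_score >= min_relative_score - 1e-9
  sites[keep, , drop = FALSE]
}

#' Gene-level motif hits across a promoter set
#'
#' Scans every window and records the sites passing the threshold; a gene
#' has the motif iff it retains at least one site.
#'
#' @param windows named character vector of promoter windows.
#' @param pwm a `pwm_model` or `pfm`.
#' @param min_relative_score threshold (default 0.80).
#' @param both_strands default TRUE.
#' @return list: `sites` (data.frame gene, offset, strand, score,
#'   relative_score) and `genes` (ids with >= 1 kept site).
#' @export
motif_hits <- function(windows, pwm, min_relative_score = 0.80,
                       both_strands = TRUE) {
  pwm <- pwm_from_pfm(pwm)
  per <- lapply(names(windows), function(g) {
    s <- call_hits(scan_promoter(windows[[g]], pwm, both_strands),
                   min_relative_score)
    if (nrow(s)) cbind(gene = g, s, stringsAsFactors = FALSE) else NULL
  })
  sites <- do.call(rbind, per)
  if (is.null(sites)) {
    sites <- data.frame(gene = character(0), offset = integer(0),
                        strand = character(0), score = numeric(0),
                        relative_score = numeric(0))
  }
  rownames(sites) <- NULL
  list(sites = sites, genes = unique(sites$gene))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric: draws of size `n` from a universe of
#' `N` containing `K` feature-bearing genes.
#'
#' @param N universe size.
#' @param K feature-bearing genes in the universe.
#' @param n query-set size.
#' @param k feature-bearing genes in the query.
#' @return probability in (0, 1].
#' @export
hypergeom_p <- function(N, K, n, k) {
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  if (k == 0) return(1)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

# Shared enrichment core: feature_sets is a named list of gene id vectors.
enrich_core <- function(query, universe, feature_sets) {
  universe <- unique(universe)
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warning(length(dropped), " query gene(s) not in the universe; dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  if (!length(feature_sets) || n == 0L) {
    return(data.frame(id = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      padj = numeric(0)))
  }
  rows <- lapply(names(feature_sets), function(id) {
    set <- intersect(unique(feature_sets[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    data.frame(id = id, N = N, K = K, n = n, k = k,
               p = hypergeom_p(N, K, n, k), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$p)
  out <- out[order(out$p, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif enrichment between gene sets
#'
#' For each motif, assembles the N/K/n/k contingency from gene-level hit
#' flags and computes the hypergeometric upper tail, BH-adjusted across
#' motifs.
#'
#' @param query character vector of query gene ids.
#' @param universe character vector of universe gene ids.
#' @param hits named list: motif id -> gene ids with >= 1 hit (the `genes`
#'   element of [motif_hits()]).
#' @return data.frame: id, N, K, n, k, p, padj (sorted by p).
#' @export
enrich_motifs <- function(query, universe, hits) {
  enrich_core(query, universe, hits)
}

#' Over-representation analysis over a term mapping
#'
#' Identical machinery to [enrich_motifs()] applied to term membership;
#' terms with fewer than 2 universe genes are skipped.
#'
#' @param query,universe character vectors of gene ids.
#' @param term_map data.frame with columns gene, term.
#' @return data.frame: id, N, K, n, k, p, padj.
#' @export
ora_enrichment <- function(query, universe, term_map) {
  sets <- split(term_map$gene, term_map$term)
  keep <- vapply(sets, function(g) {
    length(intersect(unique(g), unique(universe))) >= 2L
  }, logical(1))
  enrich_core(query, universe, sets[keep])
}
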