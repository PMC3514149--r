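# JASPAR parsing, PWM construction and scanning, hypergeometric enrichment.

test_that("JASPAR parser: both dialects, round trip, malformed input", {
  bracketed <- c(">MA0001 TOY",
                 "A [ 4 0 1 ]",
                 "C [ 0 4 1 ]",
                 "G [ 0 0 1 ]",
                 "T [ 0 0 1 ]")
  plain <- c(">MA0001 TOY",
             "4 0 1",
             "0 4 1",
             "0 0 1",
             "0 0 1")
  f1 <- withr::local_tempfile(fileext = ".jaspar")
  f2 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(bracketed, f1)
  writeLines(plain, f2)
  p1 <- read_jaspar(f1)
  p2 <- read_jaspar(f2)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$counts, p2[[1]]$counts)
  expect_equal(ncol(p1[[1]]$counts), 3)
  expect_equal(rownames(p1[[1]]$counts), c("A", "C", "G", "T"))

  # shuffled labelled rows parse by their base letter
  shuffled <- c(">M2 X", "T [ 1 2 ]", "A [ 3 4 ]", "G [ 5 6 ]", "C [ 7 8 ]")
  writeLines(shuffled, f1)
  p3 <- read_jaspar(f1)[[1]]
  expect_equal(p3$counts["A", ], c(3, 4))
  expect_equal(p3$counts["T", ], c(1, 2))

  # write -> read round trip preserves counts
  pfm <- toy_pfm("ACGTAC", id = "RT1")
  write_jaspar(list(pfm), f2)
  back <- read_jaspar(f2)[[1]]
  expect_equal(back$counts, pfm$counts, ignore_attr = TRUE)
  expect_equal(back$id, "RT1")

  writeLines(c(">M3 BAD", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"),
             f1)
  expect_error(read_jaspar(f1), "ragged")
  writeLines(c(">M4 BAD", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), f1)
  expect_error(read_jaspar(f1), "missing base")
})

test_that("PWM weights: uniform column, hand arithmetic, consensus maximum", {
  uni <- matrix(1, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  pw <- pwm_from_pfm(uni)
  expect_equal(unname(pw$weights), matrix(0, 4, 2), tolerance = 1e-12)

  col <- matrix(c(4, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"),
                                                     NULL))
  pw2 <- pwm_from_pfm(col, pseudocount = 0.8)
  expect_equal(round(unname(pw2$weights["A", 1]), 3), round(log2(3.5), 3))

  # consensus sequence attains score_max / relative score 1
  pfm <- toy_pfm("TGACGT")
  pw3 <- pwm_from_pfm(pfm)
  hit <- scan_promoter("TGACGT", pw3, both_strands = FALSE)
  expect_equal(hit$score, pw3$score_max, tolerance = 1e-9)
  expect_equal(hit$relative_score, 1, tolerance = 1e-9)
  expect_equal(pw3$consensus, "TGACGT")

  expect_error(pwm_from_pfm(pfm, pseudocount = 0), "positive")
  expect_error(pwm_from_pfm(pfm, background = c(A = 0.5, C = 0.5, G = 0.2,
                                                T = 0.2)), "summing to 1")
})

test_that("scanning equals brute-force summation on both strands", {
  set.seed(6)
  window <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  pfm <- toy_pfm("ACGT", strong = 7, weak = 2)
  pw <- pwm_from_pfm(pfm)
  sites <- scan_promoter(window, pw)
  expect_equal(nrow(sites), 17 * 2)

  # longhand per-site summation over the weight matrix
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(seq_along(ch), function(j) pw$weights[ch[j], j], numeric(1)))
  }
  for (r in seq_len(nrow(sites))) {
    sub <- substr(window, sites$offset[r] + 1, sites$offset[r] + 4)
    if (sites$strand[r] == "-") sub <- revcomp(sub)
    expect_equal(sites$score[r], score_one(sub), tolerance = 1e-9)
  }

  # strand symmetry: scanning the reverse complement permutes the sites
  # but keeps the multiset of scores
  sites_rc <- scan_promoter(revcomp(window), pw)
  expect_equal(sort(sites_rc$score), sort(sites$score), tolerance = 1e-9)

  # relative scores bounded in [0, 1] on a long random window
  set.seed(60)
  big <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  sb <- scan_promoter(big, pw)
  expect_true(all(sb$relative_score >= -1e-9 & sb$relative_score <= 1 + 1e-9))

  expect_error(scan_promoter("ACG", pw), "shorter")
  # sites containing N are skipped
  sn <- scan_promoter("ACGTNACGT", pw, both_strands = FALSE)
  expect_equal(sn$offset, c(0L, 5L))
})

test_that("hit thresholding keeps everything at 0 and only consensus at 1", {
  pw <- pwm_from_pfm(toy_pfm("TTAACC"))
  win <- paste0("GGGG", "TTAACC", "GGGG")
  sites <- scan_promoter(win, pw)
  expect_equal(nrow(call_hits(sites, 0)), nrow(sites))
  # two consensus-equal sites: the planted one and its reverse-strand
  # reading of GGTTAA at offset 2
  top <- call_hits(sites, 1)
  expect_equal(top$offset, c(2L, 4L))
  expect_equal(top$strand, c("-", "+"))
  expect_equal(top$relative_score, c(1, 1), tolerance = 1e-9)
})

test_that("hypergeometric tail: closed forms, enumeration oracle, monotonicity", {
  expect_equal(hypergeom_p(100, 10, 20, 0), 1)
  expect_equal(hypergeom_p(10, 5, 5, 5), 1 / choose(10, 5), tolerance = 1e-12)

  # enumeration over all C(20, 6) draws
  draws <- utils::combn(20, 6)
  k_obs <- colSums(draws <= 8)   # genes 1..8 carry the feature
  p_enum <- mean(k_obs >= 4)
  expect_equal(hypergeom_p(20, 8, 6, 4), p_enum, tolerance = 1e-12)

  ps <- vapply(0:6, function(k) hypergeom_p(20, 8, 6, k), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_p(10, 12, 5, 2), "inconsistent")
})

test_that("motif enrichment: degenerate cases and planted fixture", {
  universe <- sprintf("g%03d", 1:100)
  all_hit <- list(M = universe)
  expect_equal(enrich_motifs(universe[1:20], universe, all_hit)$p, 1)
  expect_equal(enrich_motifs(universe, universe,
                             list(M = universe[1:30]))$p, 1)

  # planted fixture: instances in 40 of 200 foreground genes, none in the
  # 800 background genes
  pfm <- toy_pfm("TGACGTCATCGA", id = "PLANTED")
  decoy <- toy_pfm("CATTGAGGCATT", id = "DECOY")
  fg <- sprintf("gene%05d", 1:200)
  prom <- simulate_promoters(1000, flank = 300, gc_background = 0.4,
                             motif_models = list(pfm),
                             planted_per_motif = 40, motif_genes = fg,
                             seed = 3)
  w <- extract_window(prom$tss, prom$sequences, 200, 50)
  hits <- list(PLANTED = motif_hits(w, pfm, 0.8)$genes,
               DECOY = motif_hits(w, decoy, 0.8)$genes)
  enr <- enrich_motifs(fg, names(w), hits)
  expect_lt(enr$p[enr$id == "PLANTED"], 1e-6)
  expect_gt(enr$p[enr$id == "DECOY"], 0.05)
  # >= 90% of planted genes flagged, <= 10% of background genes flagged
  planted_genes <- unique(prom$motifs$gene)
  expect_gte(mean(planted_genes %in% hits$PLANTED), 0.9)
  bg <- setdiff(names(w), fg)
  expect_lte(mean(bg %in% hits$PLANTED), 0.1)
  # BH preserves the p-value ordering
  expect_equal(order(enr$p), order(enr$padj))
})

test_that("ORA: whole-universe term, contained term, empty query", {
  universe <- sprintf("g%02d", 1:50)
  tm <- rbind(data.frame(gene = universe, term = "ALL"),
              data.frame(gene = universe[1:5], term = "SMALL"))
  res <- ora_enrichment(universe[1:10], universe, tm)
  expect_equal(res$p[res$id == "ALL"], 1)
  # SMALL is fully contained in the query
  expect_equal(res$p[res$id == "SMALL"],
               hypergeom_p(50, 5, 10, 5), tolerance = 1e-12)
  expect_equal(nrow(ora_enrichment(character(0), universe, tm)), 0)
  # terms with K < 2 are skipped
  tm2 <- rbind(tm, data.frame(gene = universe[1], term = "SINGLETON"))
  expect_false("SINGLETON" %in% ora_enrichment(universe[1:10], universe,
                                               tm2)$id)
})
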