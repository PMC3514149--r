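# TSS window extraction, GC/CpG scoring, classification, chi-square.

test_that("window extraction: coordinates, strand symmetry, slicing oracle", {
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  tss_plus <- data.frame(gene = "g1", chrom = "c1", tss = 100, strand = "+")
  w <- extract_window(tss_plus, c(c1 = s), 100, 100)
  expect_equal(unname(w), substr(s, 1, 200))

  # the same gene annotated on the reverse complement yields the same window
  rc <- revcomp(s)
  tss_minus <- data.frame(gene = "g1", chrom = "c1",
                          tss = nchar(s) - 1 - 100, strand = "-")
  w2 <- extract_window(tss_minus, c(c1 = rc), 100, 100)
  expect_equal(unname(w2), unname(w))

  # random records vs an independent Biostrings-based slicing oracle
  set.seed(4)
  for (i in 1:300) {
    L <- sample(260:400, 1)
    seqs <- c(chr = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = ""))
    strand <- sample(c("+", "-"), 1)
    pos <- sample(110:(L - 110), 1)
    tss <- data.frame(gene = "g", chrom = "chr", tss = pos, strand = strand)
    got <- unname(extract_window(tss, seqs, 100, 100))
    expect_equal(nchar(got), 200)
    oracle <- if (strand == "+") {
      unname(substr(seqs, pos - 100 + 1, pos + 100))
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(seqs, pos - 100 + 2, pos + 100 + 1))))
    }
    expect_equal(got, oracle)
  }
})

test_that("window extraction: bounds error by default, truncation with clip", {
  seqs <- c(c1 = strrep("ACGT", 50))   # 200 bases
  tss <- data.frame(gene = "g", chrom = "c1", tss = 50, strand = "+")
  expect_error(extract_window(tss, seqs, 100, 100), "extends past")
  expect_warning(w <- extract_window(tss, seqs, 100, 100, clip = TRUE),
                 "clipping")
  expect_equal(nchar(unname(w)), 150)
  expect_error(extract_window(data.frame(gene = "g", chrom = "nope",
                                         tss = 50, strand = "+"),
                              seqs, 10, 10), "not found")
})

test_that("GC content: boundary values, N handling, counting oracle", {
  expect_equal(unname(gc_content(strrep("A", 200))), 0)
  expect_equal(unname(gc_content(strrep("CG", 100))), 1)
  # N counts toward length, not the numerator
  expect_equal(unname(gc_content("CCNN")), 0.5)
  set.seed(6)
  w <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  tally <- table(strsplit(w, "")[[1]])
  expect_equal(unname(gc_content(w)),
               unname((tally["C"] + tally["G"]) / 200))
  expect_error(gc_content(""), "empty")
})

test_that("CpG score: hand-counted dinucleotides and the literal variant", {
  # "CG" x 100: 100 CG dinucleotides, 100 C, 100 G
  expect_equal(unname(cpg_score(strrep("CG", 100))), 2.0)
  # C^100 G^100: single CG at the junction
  expect_equal(unname(cpg_score(paste0(strrep("C", 100), strrep("G", 100)))),
               1 * 200 / (100 * 100))
  expect_equal(unname(cpg_score(strrep("A", 200))), 0)
  # overlapping scan: CGCG has 2 CGs
  expect_equal(unname(cpg_score("CGCG")), 2 * 4 / (2 * 2))
  # the literal printed form is bounded by 1/L
  lit <- cpg_score(strrep("CG", 100), literal = TRUE)
  expect_equal(unname(lit), 100 / (100 * 100 * 200))
  expect_lt(lit, 1 / 200)
})

test_that("CpG score is invariant under reverse complement", {
  set.seed(13)
  for (i in 1:200) {
    w <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    expect_equal(unname(cpg_score(revcomp(w))), unname(cpg_score(w)))
  }
})

test_that("classification uses strict inequalities on both thresholds", {
  expect_false(classify_cpg(0.5, 2.0))
  expect_false(classify_cpg(0.6, 0.6))
  expect_true(classify_cpg(0.8, 2.0))
  expect_false(classify_cpg(0.51, 0.59))
})

test_that("proportion comparison matches the hand formula and chi-square oracle", {
  eq <- compare_proportions(c(50, 50), c(100, 100))
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p.value, 1, tolerance = 1e-12)

  cmp <- compare_proportions(c(30, 60), c(100, 100))
  expect_equal(round(cmp$statistic, 2), 18.18)
  expect_equal(cmp$df, 1)

  # three groups, identical proportions -> statistic 0, df 2
  tri <- compare_proportions(c(10, 20, 30), c(50, 100, 150))
  expect_equal(tri$statistic, 0, tolerance = 1e-12)
  expect_equal(tri$df, 2)

  # random 2x2 tables vs longhand sum((O-E)^2 / E)
  set.seed(17)
  for (i in 1:100) {
    tot <- sample(20:200, 2)
    pos <- c(sample(1:(tot[1] - 1), 1), sample(1:(tot[2] - 1), 1))
    got <- compare_proportions(pos, tot)$statistic
    O <- rbind(pos, tot - pos)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(got, sum((O - E)^2 / E), tolerance = 1e-9)
  }
  expect_warning(compare_proportions(c(0, 1), c(2, 2)), "below 1")
  expect_error(compare_proportions(c(5, 1), c(4, 2)), "lie in")
})
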