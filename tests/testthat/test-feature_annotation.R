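# Promoter/downstream windows, priority feature assignment, accessibility
# calls and TSS metagene profiles.

test_that("promoter windows are strand-mirrored and clip at sequence bounds", {
  gp <- gene_models("g1", "chr1", 5000L, 8000L, "+")
  expect_equal(promoter_interval(gp[1, ]), c(3500L, 5000L))
  gm <- gene_models("g2", "chr1", 2000L, 5001L, "-")  # tss = 5000
  expect_equal(promoter_interval(gm[1, ]), c(5001L, 6501L))
  gc <- gene_models("g3", "chr1", 100L, 900L, "+")
  expect_equal(promoter_interval(gc[1, ], chrom_length = 10000L), c(0L, 100L))
  expect_error(promoter_interval(gp[1, ], upstream = 0), "> 0")
})

test_that("downstream windows extend past the TTS away from the gene body", {
  gp <- gene_models("g1", "chr1", 5000L, 8001L, "+")   # tts = 8000
  expect_equal(downstream_interval(gp[1, ]), c(8001L, 11001L))
  gm <- gene_models("g2", "chr1", 2000L, 5000L, "-")   # tts = 2000
  expect_equal(downstream_interval(gm[1, ]), c(0L, 2000L))
  expect_error(downstream_interval(gp[1, ], len = 0), "> 0")
})

test_that("promoter beats exon and intron; no overlap means intergenic", {
  # gene A body [10000, 14000) with an intron; gene B promoter covers
  # [17500, 19000) just downstream of A
  genes <- gene_models(
    c("gA", "gB"), "chr1", c(10000L, 19000L), c(14000L, 22000L), c("+", "+"),
    exons = list(cbind(start = c(10000L, 13000L), end = c(11000L, 14000L)),
                 cbind(start = 19000L, end = 22000L)))
  # peak inside gene A's intron and gene B's promoter window
  res <- assign_features(data.frame(chrom = "chr1", start = 12800L,
                                    end = 12900L), genes,
                         upstream = 1500L, downstream = 3000L)
  expect_equal(res$feature, "intron")  # B's promoter is [17500,19000): no hit
  res2 <- assign_features(data.frame(chrom = "chr1", start = 16900L,
                                     end = 17600L), genes)
  # overlaps A's downstream window [14000,17001) and B's promoter
  # [17500,19000): promoter wins
  expect_equal(res2$feature, "promoter")
  expect_equal(res2$gene_id, "gB")
  res3 <- assign_features(data.frame(chrom = "chr1", start = 500000L,
                                     end = 500100L), genes)
  expect_equal(res3$feature, "intergenic")
  expect_true(is.na(res3$gene_id))
})

test_that("feature assignment agrees with brute-force enumeration", {
  set.seed(21)
  genes <- toy_genes(n = 40, spacing = 6000, seed = 21)
  peaks <- data.frame(chrom = "chr1",
                      start = sample(0:260000, 300, replace = TRUE))
  peaks$end <- peaks$start + sample(50:600, 300, replace = TRUE)
  got <- assign_features(peaks, genes)
  for (i in seq_len(nrow(peaks))) {
    want <- oracle_assign(peaks$chrom[i], peaks$start[i], peaks$end[i], genes)
    expect_identical(got$feature[i], want$feature)
    expect_identical(got$gene_id[i], want$gene_id)
  }
})

test_that("accessibility calls match brute-force interval intersection", {
  set.seed(5)
  genes <- toy_genes(n = 20, spacing = 8000, seed = 5)
  ps <- peak_set("chr1", starts <- sample(0:170000, 60),
                 starts + sample(100:500, 60, replace = TRUE))
  for (region in c("promoter", "gene_body", "promoter_or_body")) {
    calls <- call_accessibility(ps, genes, region = region)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      prom <- if (g$strand == "+") c(g$tss - 1500, g$tss)
              else c(g$tss + 1, g$tss + 1501)
      body <- c(g$start, g$end)
      ivs <- switch(region, promoter = list(prom), gene_body = list(body),
                    promoter_or_body = list(prom, body))
      want <- any(vapply(ivs, function(iv)
        any(ps$peaks$start < iv[2] & iv[1] < ps$peaks$end), logical(1)))
      expect_equal(calls$accessible[i], want)
    }
  }
  expect_error(call_accessibility(ps, genes, region = "enhancer"))
})

test_that("accessibility is monotone under adding peaks", {
  set.seed(8)
  genes <- toy_genes(n = 15, spacing = 9000, seed = 8)
  s1 <- sample(0:130000, 20)
  ps1 <- peak_set("chr1", s1, s1 + 300)
  s2 <- c(s1, sample(0:130000, 20))
  ps2 <- peak_set("chr1", s2, s2 + 300)
  c1 <- call_accessibility(ps1, genes)
  c2 <- call_accessibility(ps2, genes)
  expect_true(all(c2$accessible >= c1$accessible))
})

test_that("gene fully covered by a peak is accessible; empty chrom is not", {
  genes <- gene_models("g1", "chr1", 50000L, 52000L, "+")
  full <- peak_set("chr1", 40000L, 60000L)
  expect_true(call_accessibility(full, genes)$accessible)
  other <- peak_set("chr9", 40000L, 60000L)
  expect_false(call_accessibility(other, genes)$accessible)
})

test_that("metagene profile handles full, empty and strand-flipped coverage", {
  gp <- gene_models("g1", "chr1", 50000L, 55000L, "+")
  full <- peak_set("chr1", 40000L, 60000L)
  pr <- metagene_profile(full, gp, window = 1000L, binwidth = 10L)
  expect_equal(pr$values, rep(1, 200))
  empty <- peak_set("chr1", 900000L, 900100L)
  expect_equal(metagene_profile(empty, gp, window = 1000L)$values, rep(0, 200))

  # minus-strand gene, peak only genomically after the TSS (= upstream):
  # signal must land on the left (upstream) half
  gm <- gene_models("g2", "chr1", 40000L, 50001L, "-")  # tss = 50000
  up <- peak_set("chr1", 50200L, 50800L)
  prm <- metagene_profile(up, gm, window = 1000L, binwidth = 10L)
  left <- prm$values[prm$offsets < 0]
  right <- prm$values[prm$offsets >= 0]
  expect_gt(sum(left), 0)
  expect_equal(sum(right), 0)
  expect_true(all(prm$values >= 0 & prm$values <= 1))

  expect_error(metagene_profile(full, gp[0, ]), "at least one gene")
  expect_error(metagene_profile(full, gp, window = 1000L, binwidth = 7L),
               "divisible")
})

test_that("profile of a union of disjoint gene sets is the weighted mean", {
  set.seed(13)
  gA <- toy_genes(n = 6, spacing = 7000, seed = 13)
  gB <- toy_genes(n = 4, spacing = 7500, seed = 14)
  gB$gene_id <- paste0(gB$gene_id, "_B")
  gB$start <- gB$start + 300000L; gB$end <- gB$end + 300000L
  gB$tss <- gB$tss + 300000L; gB$tts <- gB$tts + 300000L
  both <- rbind(gA, gB)
  st <- sample(0:340000, 80)
  ps <- peak_set("chr1", st, st + sample(100:800, 80, replace = TRUE))
  pA <- metagene_profile(ps, gA); pB <- metagene_profile(ps, gB)
  pAB <- metagene_profile(ps, both)
  expect_equal(pAB$values, (6 * pA$values + 4 * pB$values) / 10)
})
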