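test_that("the fold rule classifies regions as stated, with pseudocount", {
  m <- make_rpkm_matrix(rbind(c(4, 4, 10, 10),
                              c(5, 5, 5, 5),
                              c(3, 3, 0, 0)),
                        groups = c(a = "ctrl", b = "ctrl",
                                   c = "case", d = "case"))
  d <- call_ders(m, fold = 2, eps = 0.5)
  expect_equal(nrow(d), 2L)
  gain <- d[d$class == "GAIN", ]
  expect_equal(gain$mean_ctrl, 4)
  expect_equal(gain$log2fc, log2(10.5 / 4.5), tolerance = 1e-12)
  loss <- d[d$class == "LOSS", ]
  expect_equal(loss$log2fc, log2(0.5 / 3.5), tolerance = 1e-12)
  expect_error(call_ders(m, fold = 1), "exceed 1")
})

test_that("DER calling matches the brute-force oracle on random matrices", {
  set.seed(11)
  for (rep in 1:200) {
    nr <- sample(2:8, 1)
    groups <- c(s1 = "ctrl", s2 = "ctrl", s3 = "case", s4 = "case")
    rpkm <- matrix(stats::rexp(nr * 4, 1 / 5), nr, 4)
    rpkm[sample(length(rpkm), nr)] <- 0   # exercise zero-signal regions
    m <- make_rpkm_matrix(rpkm, groups)
    d <- call_ders(m)
    want <- vapply(seq_len(nr), function(i) {
      oracle_der_class(mean(rpkm[i, 1:2]), mean(rpkm[i, 3:4]))
    }, "")
    got <- setNames(rep(NA_character_, nr), m$regions$region_id)
    got[d$region_id] <- d$class
    expect_equal(unname(got), want)
  }
})

test_that("swapping group labels swaps GAIN and LOSS exactly", {
  set.seed(3)
  rpkm <- matrix(stats::rexp(40, 1 / 5), 10, 4)
  g1 <- c(s1 = "ctrl", s2 = "ctrl", s3 = "case", s4 = "case")
  g2 <- c(s1 = "case", s2 = "case", s3 = "ctrl", s4 = "ctrl")
  d1 <- call_ders(make_rpkm_matrix(rpkm, g1))
  d2 <- call_ders(make_rpkm_matrix(rpkm, g2))
  expect_setequal(d1$region_id[d1$class == "GAIN"],
                  d2$region_id[d2$class == "LOSS"])
  expect_setequal(d1$region_id[d1$class == "LOSS"],
                  d2$region_id[d2$class == "GAIN"])
})

test_that("raising the fold threshold never adds a DER", {
  set.seed(5)
  rpkm <- matrix(stats::rexp(200, 1 / 5), 50, 4)
  g <- c(s1 = "ctrl", s2 = "ctrl", s3 = "case", s4 = "case")
  m <- make_rpkm_matrix(rpkm, g)
  prev <- call_ders(m, fold = 1.2)$region_id
  for (fold in c(1.5, 2, 3, 5)) {
    cur <- call_ders(m, fold = fold)$region_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("RPKM follows its definition and is library-scale invariant", {
  regions <- data.frame(region_id = "r1", chrom = "chr1",
                        start = 0L, end = 1000L)
  set.seed(1)
  inside <- data.frame(chrom = "chr1",
                       start = sample(0:900, 50, TRUE))
  inside$end <- inside$start + 50L
  outside <- data.frame(chrom = "chr1",
                        start = sample(2000:99000, 999950, TRUE))
  outside$end <- outside$start + 50L
  lib <- rbind(inside, outside)       # exactly 1e6 fragments, 50 in-region
  m <- quantify_regions(regions, list(s1 = lib), c(s1 = "ctrl"))
  expect_equal(unname(m$rpkm[1, 1]), 50)
  doubled <- rbind(lib, lib)
  m2 <- quantify_regions(regions, list(s1 = doubled), c(s1 = "ctrl"))
  expect_equal(m2$rpkm, m$rpkm, tolerance = 1e-9)
  empty_lib <- lib[0, ]
  expect_error(quantify_regions(regions, list(s1 = empty_lib),
                                c(s1 = "ctrl")), "library size is zero")
})

test_that("track-mode quantification averages the bedgraph over the region", {
  regions <- data.frame(region_id = "r1", chrom = "chr1",
                        start = 100L, end = 200L)
  tr <- data.frame(chrom = "chr1", start = 0L, end = 500L, value = 7.5)
  m <- quantify_regions(regions, list(s1 = tr), c(s1 = "ctrl"),
                        mode = "track")
  expect_equal(unname(m$rpkm[1, 1]), 7.5)
  # partial coverage: half the region at 4, rest uncovered (0)
  tr <- data.frame(chrom = "chr1", start = 100L, end = 150L, value = 4)
  m <- quantify_regions(regions, list(s1 = tr), c(s1 = "ctrl"),
                        mode = "track")
  expect_equal(unname(m$rpkm[1, 1]), 2)
})

test_that("feature annotation follows the stated midpoint precedence", {
  genes <- toy_genes(tss = 5000L, strand = "+", len = 1000L, ids = "gA")
  # midpoint exactly at the TSS
  r <- data.frame(chrom = "chr1", start = 4990L, end = 5010L)
  a <- annotate_feature(r, genes)
  expect_equal(a$feature, "promoter-TSS")
  expect_equal(a$dist_tss, 0)
  # far from every gene
  r <- data.frame(chrom = "chr1", start = 49990L, end = 50010L)
  expect_equal(annotate_feature(r, genes)$feature, "intergenic")
  # intron: gene [1000,2000)+ with exon [1000,1200), midpoint 1500
  g <- toy_genes(tss = 1000L, strand = "+", len = 1000L, ids = "gB")
  g$exon_starts <- "1000,1900"; g$exon_ends <- "1200,2000"
  r <- data.frame(chrom = "chr1", start = 1480L, end = 1520L)
  expect_equal(annotate_feature(r, g)$feature, "intron")
  r <- data.frame(chrom = "chr1", start = 1130L, end = 1170L)
  expect_equal(annotate_feature(r, g)$feature, "exon")
  # TES proximity beats exon/intron
  r <- data.frame(chrom = "chr1", start = 1930L, end = 1970L)
  expect_equal(annotate_feature(r, g)$feature, "TES")
  # empty gene set
  a <- annotate_feature(r, g[0, ])
  expect_equal(a$feature, "intergenic")
  expect_equal(a$dist_tss, Inf)
})

test_that("signed TSS distance is strand-oriented", {
  gp <- toy_genes(tss = 5000L, strand = "+", ids = "gp")
  gm <- toy_genes(tss = 5000L, strand = "-", ids = "gm")
  r <- data.frame(chrom = "chr1", start = 4790L, end = 4810L)  # mid 4800
  expect_equal(annotate_feature(r, gp)$dist_tss, -200)  # upstream of +
  expect_equal(annotate_feature(r, gm)$dist_tss, 200)   # downstream of -
})

test_that("distance summary bins and chromosome counts are consistent", {
  d <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(0L, 0L, 0L), end = c(10L, 10L, 10L),
                  class = c("GAIN", "GAIN", "LOSS"),
                  dist_tss = c(200, -5000, 60000),
                  feature = c("promoter-TSS", "intergenic", "intergenic"))
  s <- distance_summary(d)
  gain <- s$distance[s$distance$class == "GAIN", ]
  expect_equal(gain$Freq[gain$bin == "0-1kb"], 0.5)
  expect_equal(sum(gain$Freq), 1)
  expect_equal(sum(s$chromosomes$Freq), 3)
  expect_equal(nrow(distance_summary(d[0, ])$distance), 0L)
})

test_that("meta profiles reproduce constant and localized tracks", {
  assets <- toy_assets(c(chr1 = paste(rep("A", 10000), collapse = "")))
  genes <- toy_genes(tss = 4000L, strand = "+", len = 2000L, ids = "g1")
  tr <- data.frame(chrom = "chr1", start = 0L, end = 10000L, value = 3)
  mp <- meta_profile(tr, genes, assets, upstream = 400L, downstream = 400L,
                     body_bins = 50L, bin = 20L)
  expect_equal(length(mp$values), 20L + 50L + 20L)
  expect_true(all(abs(mp$values - 3) < 1e-12))

  tr <- data.frame(chrom = "chr1", start = 4000L, end = 4040L, value = 1)
  mp <- meta_profile(tr, genes, assets, upstream = 400L, downstream = 400L,
                     body_bins = 50L, bin = 20L)
  body <- mp$values[mp$section == "body"]
  expect_equal(body[1], 1)
  expect_true(all(body[-1] == 0))
  expect_true(all(mp$values[mp$section == "upstream"] == 0))

  # strand mirroring: same gene on -, signal at its TSS end
  gm <- toy_genes(tss = 5999L, strand = "-", len = 2000L, ids = "g2")
  tr <- data.frame(chrom = "chr1", start = 5960L, end = 6000L, value = 1)
  mp <- meta_profile(tr, gm, assets, upstream = 400L, downstream = 400L,
                     body_bins = 50L, bin = 20L)
  expect_equal(mp$values[mp$section == "body"][1], 1)

  # short genes are skipped with a count
  gshort <- toy_genes(tss = 100L, strand = "+", len = 30L, ids = "tiny")
  mp <- meta_profile(tr, gshort, assets, body_bins = 50L)
  expect_equal(mp$n_skipped, 1L)
})

test_that("DER-centered profiles localize planted signal at the summit", {
  assets <- toy_assets(c(chr1 = paste(rep("A", 10000), collapse = "")))
  ders <- data.frame(chrom = "chr1", start = 4800L, end = 5200L,
                     summit = 5000L)
  tr <- data.frame(chrom = "chr1", start = 4950L, end = 5050L, value = 2)
  p <- der_center_profile(tr, ders, assets, flank = 400L, bin = 20L)
  expect_equal(length(p$values), 40L)
  expect_equal(p$position[which.max(p$values)] %in% seq(-60, 40, 20), TRUE)
  # 100 bp of signal spanning 6 bins (two partial edge bins)
  expect_equal(sum(p$values > 0), 6L)
})

test_that("consensus construction unions and records contributing samples", {
  p1 <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  p2 <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  cons <- build_consensus(list(a = p1, b = p2))
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 0L)
  expect_equal(cons$end, 150L)
  expect_equal(cons$samples, "a,b")
  # identical sets reproduce the set; disjoint sets concatenate
  cons <- build_consensus(list(a = p1, b = p1))
  expect_equal(nrow(cons), 1L)
  p3 <- data.frame(chrom = "chr2", start = 0L, end = 50L)
  cons <- build_consensus(list(a = p1, b = p3))
  expect_equal(nrow(cons), 2L)
  expect_error(build_consensus(list(a = p1[0, ])), "no peaks")
})
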