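test_that("PWM scoring matches the log-odds formula on a point-mass motif", {
  m <- pwm_from_consensus("ACGG")   # non-palindromic on purpose
  # each consensus base has probability 1.01/1.04 after pseudocounting
  expect_equal(m$max_score, 4 * log2((1.01 / 1.04) / 0.25),
               tolerance = 1e-12)
  hits <- scan_pwm("ACGG", m)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, m$max_score, tolerance = 1e-12)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$strand, "+")
  # the reverse complement scores the same on the minus strand
  rc <- scan_pwm(revcomp("ACGG"), m)
  expect_equal(rc$strand, "-")
  expect_equal(rc$score, m$max_score, tolerance = 1e-12)
  # a palindromic site is reported once per strand
  pal <- scan_pwm("ACGT", pwm_from_consensus("ACGT"))
  expect_setequal(pal$strand, c("+", "-"))
  # sequences shorter than the motif yield no hits, not an error
  expect_equal(nrow(scan_pwm("AC", m)), 0L)
})

test_that("N bases score as background and do not create hits", {
  m <- pwm_from_consensus("ACGTACGT")
  expect_equal(nrow(scan_pwm("ACGNNNGT", m)), 0L)
  # a single N inside an otherwise perfect site loses one base's worth
  hits <- scan_pwm("ACGTACGT", m)
  hitsN <- scan_pwm("ACGTNCGT", m, threshold_frac = 0.5)
  expect_equal(hitsN$score[1],
               hits$score[1] - log2((1.01 / 1.04) / 0.25),
               tolerance = 1e-12)
})

test_that("the vectorized scanner equals the naive per-position oracle", {
  set.seed(17)
  m <- pwm(matrix(c(8, 1, 1, 0,
                    0, 9, 1, 0,
                    1, 0, 8, 1,
                    2, 2, 2, 4), 4, 4, byrow = TRUE,
                 dimnames = list(c("A", "C", "G", "T"), NULL)),
           name = "mixed")
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    got <- scan_pwm(s, m, threshold_frac = 0.6, collapse = FALSE)
    want <- naive_scan(s, m, threshold_frac = 0.6)
    want <- want[order(want$offset, want$strand), ]
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("overlapping same-strand hits collapse to the best-scoring one", {
  m <- pwm_from_consensus("AAAA")
  # "AAAAA" has two overlapping perfect-threshold windows at 0 and 1
  hits <- scan_pwm("AAAAA", m, threshold_frac = 0.9)
  expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
  raw <- scan_pwm("AAAAA", m, threshold_frac = 0.9, collapse = FALSE)
  expect_equal(nrow(raw[raw$strand == "+", ]), 2L)
})

test_that("multi-sequence scanning never crosses window boundaries", {
  m <- pwm_from_consensus("ACGTAC")
  # the junction of these two windows spells the motif; no hit may appear
  hits <- scan_pwm(c("TTTACG", "TACTTT"), m)
  expect_equal(nrow(hits), 0L)
  hits <- scan_pwm(c("TACGTACT", "GGACGTACGG"), m)
  expect_equal(sort(unique(hits$seq_index)), c(1L, 2L))
})

test_that("summit windows center on summits, clip at edges, fall back to midpoints", {
  assets <- random_genome(2000L, seed = 2)
  r <- data.frame(region_id = c("a", "b"), chrom = "chr1",
                  start = c(900L, 0L), end = c(1100L, 100L),
                  summit = c(1000L, 50L))
  w <- summit_windows(r, assets, halfwidth = 200L)
  expect_equal(w$start, c(800L, 0L))
  expect_equal(w$end, c(1200L, 250L))
  expect_equal(nchar(w$seq), w$end - w$start)
  r$summit <- NULL
  w2 <- summit_windows(r, assets, halfwidth = 100L)
  expect_equal(w2$start[1], 900L)  # midpoint fallback
})

test_that("motif enrichment reduces to the closed-form binomial tail", {
  m <- pwm_from_consensus("ACGTACGTAC")
  with_site <- function(n) replicate(n, paste0("TTTTT", "ACGTACGTAC", "GGGGG"))
  without <- function(n) replicate(n, paste(rep("T", 20), collapse = ""))
  # k = 10/10 targets, background 2/40 -> p0 = 0.05, p = 0.05^10
  res <- motif_enrichment(with_site(10), c(with_site(2), without(38)),
                          list(m))
  expect_equal(res$k, 10L)
  expect_equal(res$p, 0.05^10, tolerance = 1e-9)
  expect_true(res$significant)
  # equal target and background fractions are not enriched
  res <- motif_enrichment(c(with_site(5), without(5)),
                          c(with_site(20), without(20)), list(m))
  expect_gte(res$p, 0.5)
  expect_error(motif_enrichment(with_site(1), without(1), list()), "empty")
})

test_that("reverse-complementing every window leaves enrichment unchanged", {
  set.seed(23)
  m <- pwm_from_consensus("TGACTCAGCA")
  rnd <- function(n) replicate(n, paste(sample(c("A", "C", "G", "T"), 60,
                                               TRUE), collapse = ""))
  tg <- c(replicate(6, paste0("AAAAA", "TGACTCAGCA", "CCCCC")), rnd(14))
  bg <- rnd(50)
  a <- motif_enrichment(tg, bg, list(m))
  b <- motif_enrichment(revcomp(tg), revcomp(bg), list(m))
  expect_equal(a$k, b$k)
  expect_equal(a$k_bg, b$k_bg)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("DETF identification gates on enrichment, significance and sign", {
  enr <- data.frame(motif = c("m1", "m2", "m3"), tf = c("TF1", "TF2", "TF3"),
                    p = c(0.001, 0.5, 0.004))
  expr <- data.frame(gene_id = c("TF1", "TF2", "TF3", "TF4"),
                     mean_ctrl = c(1, 1, 8, 1), mean_case = c(7, 9, 1, 1),
                     log2fc = c(2.8, 3.2, -3, 0),
                     significant = c(TRUE, TRUE, TRUE, FALSE))
  empty <- enr[0, ]
  up <- identify_detfs(enr, empty, expr)
  # m2 fails the motif gate; m3 is enriched but downregulated
  expect_equal(up$tf, "TF1")
  expect_equal(up$direction, "up")
  expect_equal(up$expression_level, log2(7 + 1))
  down <- identify_detfs(empty, enr, expr)
  expect_equal(down$tf, "TF3")
  # enriched TF without a significant expression change is not a DETF
  expr$significant[1] <- FALSE
  expect_equal(nrow(identify_detfs(enr, empty, expr)), 0L)
  # unmappable TF names are counted
  # both enriched TFs (TF1, TF3) are absent from the map
  res <- identify_detfs(enr, empty, expr,
                        tf_map = data.frame(tf = "TF9", gene_id = "g9"))
  expect_equal(attr(res, "n_unmapped"), 2L)
})

test_that("occurrence profiles conserve hit counts and localize planted sites", {
  assets <- toy_assets(c(chr1 = paste(rep("T", 4000), collapse = "")))
  seqs <- as.character(assets$seq)
  # plant one site exactly at each summit of three windows
  summits <- c(1000L, 2000L, 3000L)
  m <- pwm_from_consensus("ACGTACGTAC")
  for (s in summits) substr(seqs["chr1"], s - 4L, s + 5L) <- "ACGTACGTAC"
  assets <- toy_assets(seqs)
  regions <- data.frame(region_id = paste0("r", 1:3), chrom = "chr1",
                        start = summits - 50L, end = summits + 50L,
                        summit = summits)
  prof <- occurrence_profile(m, regions, assets, halfwidth = 100L, bin = 10L)
  expect_equal(prof$n_hits, 3L)
  # conservation identity
  expect_equal(sum(prof$density) * prof$bin * prof$n_windows, prof$n_hits)
  expect_equal(prof$breaks[which.max(prof$density)], 0)
  # no hits is a valid all-zero profile
  m2 <- pwm_from_consensus("GGGGGGGGGG")
  prof2 <- occurrence_profile(m2, regions, assets, halfwidth = 100L)
  expect_true(all(prof2$density == 0))
})

test_that("TF target assignment enforces the 2 kb promoter boundary exactly", {
  base <- paste(rep("T", 30000), collapse = "")
  m <- pwm_from_consensus("ACGTACGTAC")   # L = 10, midpoint = start + 5
  tss <- c(g_in = 10000L, g_edge = 15000L, g_out = 20000L, g_nodeg = 25000L)
  seqs <- c(chr1 = base)
  place_site <- function(seqs, mid) {
    s <- mid - 5L
    substr(seqs["chr1"], s + 1L, s + 10L) <- "ACGTACGTAC"
    seqs
  }
  seqs <- place_site(seqs, tss[["g_in"]] + 500L)     # well inside
  seqs <- place_site(seqs, tss[["g_edge"]] - 1999L)  # 1999 bp upstream: in
  seqs <- place_site(seqs, tss[["g_out"]] - 2001L)   # 2001 bp away: out
  seqs <- place_site(seqs, tss[["g_nodeg"]])         # at TSS, but not a DEG
  assets <- toy_assets(seqs)
  genes <- toy_genes(tss = unname(tss), ids = names(tss), len = 500L)
  expr <- data.frame(gene_id = names(tss), mean_ctrl = 1,
                     mean_case = c(8, 4, 6, 2),
                     log2fc = c(3, 2, 2.5, 1),
                     significant = c(TRUE, TRUE, TRUE, FALSE))
  tg <- tf_targets(m, genes, expr, assets, promoter_window = 2000L)
  expect_setequal(tg$gene_id, c("g_in", "g_edge"))
  expect_equal(tg$gene_id[1], "g_in")   # sorted by |log2fc| descending
  expect_equal(tg$closest_site[tg$gene_id == "g_edge"], 1999)
})
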