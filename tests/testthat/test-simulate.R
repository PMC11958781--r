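tiny_cfg <- function(...) {
  defaults <- list(seed = 1L, n_chroms = 2L, chrom_length = 60000L,
                   n_genes = 40L, n_regions = 80L, n_gene_sets = 5L,
                   genes_per_set = 10L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("config validation enforces the documented parameter bounds", {
  expect_error(sim_config(frac_gain = 0.7, frac_loss = 0.5), "frac_gain")
  expect_error(sim_config(p_fg = 0.1, p_bg = 0.5), "p_bg <= p_fg")
  expect_error(sim_config(rho_target = 1.5), "rho_target")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(frip = 0), "frip")
  expect_error(sim_config(effect_log2 = c(2, 1)), "effect_log2")
})

test_that("identical config and seed reproduce byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(tiny_cfg(), dir = d1)
  simulate_study(tiny_cfg(), dir = d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_study(tiny_cfg(seed = 2L), dir = d3)
  expect_false(identical(tools::md5sum(file.path(d1, "expression.tsv"))[[1]],
                         tools::md5sum(file.path(d3, "expression.tsv"))[[1]]))
})

test_that("simulated genomes match the requested base composition", {
  cfg <- sim_config(seed = 1L, n_chroms = 1L, chrom_length = 1000000L,
                    n_genes = 0L, n_regions = 0L, gc = 0.5)
  gg <- simulate_genome_and_genes(cfg)
  expect_equal(nrow(gg$genes), 0L)
  counts <- Biostrings::alphabetFrequency(gg$assets$seq)[1, c("G", "C")]
  gc_obs <- sum(counts) / 1000000
  expect_gt(gc_obs, 0.49)
  expect_lt(gc_obs, 0.51)
})

test_that("gene models from the generator satisfy their own reader", {
  gg <- simulate_genome_and_genes(tiny_cfg())
  expect_equal(nrow(gg$genes), 40L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(gg$genes, f)
  back <- read_gene_models(f, gg$assets)
  expect_equal(back, gg$genes)
  # genes are non-overlapping per chromosome
  for (ch in unique(gg$genes$chrom)) {
    g <- gg$genes[gg$genes$chrom == ch, ]
    g <- g[order(g$tx_start), ]
    expect_true(all(g$tx_start[-1] >= g$tx_end[-nrow(g)]))
  }
  expect_error(simulate_genome_and_genes(
    sim_config(n_genes = 1000L, n_chroms = 1L, chrom_length = 100000L)),
    "too small")
})

test_that("planted effects shift case counts by the configured fold", {
  cfg <- sim_config(seed = 1L, n_chroms = 2L, chrom_length = 200000L,
                    n_genes = 380L, n_regions = 120L, frac_gain = 100 / 120,
                    frac_loss = 0, effect_log2 = c(2, 2), depth = 200,
                    dispersion = 10, frip = 1)
  gg <- simulate_genome_and_genes(cfg)
  sig <- simulate_signal(cfg, gg$genes)
  gain <- sig$truth$class == "GAIN"
  expect_equal(sum(gain), 100L)
  m <- quantify_regions(sig$regions, sig$samples, sig$groups)
  ci <- m$groups == "ctrl"
  ratio <- rowMeans(m$counts[gain, !ci]) / rowMeans(m$counts[gain, ci])
  expect_gt(mean(ratio), 3.5)
  expect_lt(mean(ratio), 4.5)
})

test_that("infinite dispersion reduces to Poisson counts", {
  cfg <- sim_config(seed = 1L, n_chroms = 1L, chrom_length = 400000L,
                    n_genes = 0L, n_regions = 1000L, frac_gain = 0,
                    frac_loss = 0, depth = 200, dispersion = Inf,
                    frip = 1, n_reps = 1L)
  sig <- simulate_signal(cfg, simulate_genome_and_genes(cfg)$genes)
  m <- quantify_regions(sig$regions, sig$samples, sig$groups)
  # across regions and both samples (beta = 0 everywhere), counts are
  # Poisson(depth * u_r): the chi-square dispersion statistic is ~1
  mu <- cfg$depth * sig$truth$baseline
  disp <- mean((m$counts - cbind(mu, mu))^2 / cbind(mu, mu))
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)
})

test_that("truth tables cover every region and gene exactly once", {
  st <- simulate_study(tiny_cfg())
  expect_setequal(st$truth$regions$region_id, st$regions$region_id)
  expect_false(anyDuplicated(st$truth$regions$region_id) > 0)
  expect_setequal(st$truth$genes$gene_id, st$genes$gene_id)
  # planted regions link to unique genes within 100 kb
  planted <- st$truth$regions[st$truth$regions$class != "null", ]
  expect_false(anyDuplicated(planted$linked_gene) > 0)
  expect_true(all(planted$dist_tss <= 100000))
  expect_true(all(abs(planted$beta) >= log2(3) - 1e-9))
  # expression table satisfies the log2fc consistency invariant
  e <- st$expression
  expect_equal(e$log2fc, log2(e$mean_case / e$mean_ctrl), tolerance = 1e-9)
})

test_that("degenerate correlation targets behave as specified", {
  cfg <- tiny_cfg(rho_target = 1, expr_noise_sd = 0)
  gg <- simulate_genome_and_genes(cfg)
  sig <- simulate_signal(cfg, gg$genes)
  ex <- simulate_expression(cfg, sig$truth, gg$genes)
  planted <- sig$truth[sig$truth$class != "null", ]
  fc <- ex$expression$log2fc[match(planted$linked_gene,
                                   ex$expression$gene_id)]
  expect_equal(unname(cor(planted$beta, fc)), 1)
  expect_error(simulate_expression(tiny_cfg(rho_target = 0.7,
                                            expr_noise_sd = 0),
                                   sig$truth, gg$genes), "incompatible")
  expect_error(simulate_expression(tiny_cfg(rho_target = 1),
                                   sig$truth, gg$genes), "requires")
})

test_that("motif planting respects probabilities and window bounds", {
  cfg <- tiny_cfg(p_fg = 1, p_bg = 0, motif_offset_sd = 0)
  gg <- simulate_genome_and_genes(cfg)
  sig <- simulate_signal(cfg, gg$genes)
  win <- summit_windows(sig$regions, gg$assets, 200L)
  win$foreground <- sig$truth$class == "GAIN"
  pm <- plant_motifs(cfg, win, gg$assets)
  motif <- pwm_from_consensus(cfg$motif_consensus)
  expect_setequal(pm$truth_motifs$window_id[pm$truth_motifs$planted],
                  win$window_id[win$foreground])
  # every foreground window now carries a site centered on the summit
  fg <- win[win$foreground, ]
  seqs <- vapply(seq_len(nrow(fg)), function(i) {
    fetch_sequence(pm$assets, fg$chrom[i], fg$start[i], fg$end[i])
  }, "")
  hits <- scan_pwm(seqs, motif)
  expect_setequal(unique(hits$seq_index), seq_len(nrow(fg)))
  offs <- pm$truth_motifs$offset[pm$truth_motifs$planted]
  expect_true(all(offs == 0))
  # p_fg = p_bg = 0 leaves the genome untouched
  cfg0 <- tiny_cfg(p_fg = 0, p_bg = 0)
  pm0 <- plant_motifs(cfg0, win, gg$assets)
  expect_equal(as.character(pm0$assets$seq), as.character(gg$assets$seq))
  # motif longer than a window is rejected
  tiny_win <- win[1, ]; tiny_win$end <- tiny_win$start + 4L
  expect_error(plant_motifs(cfg, tiny_win, gg$assets), "longer")
})

test_that("the planted gene set is built from GAIN-linked upregulated DEGs", {
  st <- simulate_study(tiny_cfg())
  sets <- st$sets
  expect_equal(length(sets), 5L)
  expect_true("planted_set" %in% names(sets))
  expect_false(any(vapply(sets, anyDuplicated, 0L) > 0))
  up_gain <- st$truth$genes$gene_id[
    st$truth$genes$deg & st$truth$genes$planted_log2fc > 0 &
    st$truth$genes$linked_class %in% "GAIN"]
  overlap <- length(intersect(sets$planted_set, up_gain))
  expect_gte(overlap, 1L)
})
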