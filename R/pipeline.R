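#' Pipeline run configuration
#'
#' Bundles either a synthetic-study configuration (\code{sim}) or a set of
#' input file paths with all stage parameters.  Defaults follow the study
#' conventions: 2-fold rule with 0.5 RPKM pseudocount, 100 kb nearest-gene
#' gate, -200/+200 summit windows with motif P < 0.01, -500/+500
#' occurrence profiling, 2 kb promoter gate, hypergeometric pathway test
#' at P < 0.05 on |log2fc| > 1 genes.
#'
#' @param sim \code{\link{sim_config}} for a simulated run, or NULL.
#' @param inputs named list of paths (\code{genome, genes, peaks,
#'   fragments, expression, sets, pwms}; \code{peaks}/\code{fragments} are
#'   named vectors, one per sample) for a run on existing files.
#' @param groups named sample-to-group (\code{ctrl}/\code{case}) map;
#'   inferred from the simulation when \code{sim} is given.
#' @param fold,eps DER fold threshold and RPKM pseudocount.
#' @param max_dist nearest-gene distance gate (bp).
#' @param summit_halfwidth motif-window halfwidth (bp).
#' @param occ_halfwidth occurrence-profile halfwidth (bp).
#' @param promoter_window TF-target promoter gate (bp).
#' @param motif_threshold PWM hit threshold (fraction of max score).
#' @param motif_alpha motif enrichment significance gate.
#' @param enrich_alpha pathway significance gate.
#' @param fc_filter |log2fc| filter before pathway enrichment.
#' @param n_decoy_pwms decoy motifs in a simulated run's library.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, inputs = NULL, groups = NULL,
                       fold = 2, eps = 0.5, max_dist = 100000L,
                       summit_halfwidth = 200L, occ_halfwidth = 500L,
                       promoter_window = 2000L, motif_threshold = 0.8,
                       motif_alpha = 0.01, enrich_alpha = 0.05,
                       fc_filter = 1.0, n_decoy_pwms = 10L) {
  cfg <- as.list(environment())
  if (is.null(sim) && is.null(inputs)) {
    stop2("either a simulation config or input paths are required")
  }
  structure(cfg, class = "run_config")
}

#' Scaled-down demonstration configuration
#'
#' A small synthetic study (2 x 150 kb genome, 400 regions, 200 genes)
#' sized so the full pipeline completes in well under a minute while every
#' stage still has recoverable planted signal.
#'
#' @param seed master seed.
#' @return \code{run_config}.
#' @export
demo_config <- function(seed = 1L) {
  run_config(sim = sim_config(seed = seed, n_chroms = 2L,
                              chrom_length = 150000L, n_genes = 200L,
                              n_regions = 400L, n_gene_sets = 8L,
                              genes_per_set = 20L))
}

validate_run_config <- function(config) {
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs, use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop2("missing input file(s): ", paste(missing, collapse = ", "))
    }
    if (is.null(config$groups)) stop2("groups are required with file inputs")
  }
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate (when configured) -> consensus -> quantify ->
#' call-ders -> annotate -> integrate -> motifs -> enrich -> report,
#' writing every stage's outputs under \code{out_dir} and a manifest of
#' md5 checksums.  Identical config + inputs reproduce identical
#' checksums; the timestamped log is kept outside the manifest.
#'
#' @param config \code{\link{run_config}} (see \code{\link{demo_config}}).
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return list with the key in-memory results (\code{ders, assignments,
#'   correlation, enrichment_gain, enrichment_loss, motif_gain, detfs,
#'   manifest}, ...); the manifest is also written to
#'   \code{manifest.tsv}.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  t0 <- Sys.time()
  stage_files <- list()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  run_stage <- function(name, expr) {
    say("stage ", name, " started")
    res <- tryCatch(expr, error = function(e) {
      say("stage ", name, " FAILED: ", conditionMessage(e))
      stop2("pipeline failed at stage '", name, "': ", conditionMessage(e))
    })
    say("stage ", name, " done")
    res
  }
  out <- list(config = config)

  # -- simulate ------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim_dir <- file.path(out_dir, "input")
    study <- run_stage("simulate", simulate_study(
      config$sim, dir = sim_dir, n_decoy_pwms = config$n_decoy_pwms,
      motif_halfwidth = config$summit_halfwidth))
    stage_files$simulate <- study$files
    assets <- study$assets; genes <- study$genes
    peaks <- lapply(study$samples, function(s) study$regions)
    fragments <- study$samples
    groups <- study$groups
    expression <- study$expression
    sets <- study$sets
    pwms <- study$pwms
    out$truth <- study$truth
  } else {
    assets <- read_fasta(config$inputs$genome)
    genes <- read_gene_models(config$inputs$genes, assets)
    peaks <- lapply(config$inputs$peaks, read_intervals,
                    format = "bed3", assets = assets)
    fragments <- lapply(config$inputs$fragments, read_intervals,
                        format = "fragments", assets = assets)
    groups <- config$groups
    expression <- read_expression_table(config$inputs$expression)
    sets <- read_gene_sets(config$inputs$sets)
    pwms <- read_pfm(config$inputs$pwms)
  }

  # -- consensus -----------------------------------------------------------
  consensus <- run_stage("consensus", build_consensus(peaks))
  f_cons <- file.path(out_dir, "consensus.tsv")
  data.table::fwrite(consensus, f_cons, sep = "\t")
  stage_files$consensus <- f_cons

  # -- quantify ------------------------------------------------------------
  mat <- run_stage("quantify",
                   quantify_regions(consensus, fragments, groups))
  f_rpkm <- file.path(out_dir, "rpkm.tsv")
  data.table::fwrite(cbind(region_id = rownames(mat$rpkm),
                           as.data.frame(mat$rpkm)), f_rpkm, sep = "\t")
  stage_files$quantify <- f_rpkm

  # -- call-ders -----------------------------------------------------------
  ders <- run_stage("call-ders",
                    call_ders(mat, fold = config$fold, eps = config$eps))
  say(nrow(ders), " DERs called (",
      sum(ders$class == "GAIN"), " GAIN / ",
      sum(ders$class == "LOSS"), " LOSS)")
  out$ders <- ders

  # -- annotate ------------------------------------------------------------
  ders <- run_stage("annotate", annotate_feature(ders, genes))
  out$ders <- ders
  out$der_summary <- distance_summary(ders)
  f_ders <- file.path(out_dir, "ders.tsv")
  data.table::fwrite(ders, f_ders, sep = "\t")
  f_gain <- file.path(out_dir, "ders_gain.bed")
  f_loss <- file.path(out_dir, "ders_loss.bed")
  write_intervals(ders[ders$class == "GAIN",
                       c("chrom", "start", "end")], f_gain)
  write_intervals(ders[ders$class == "LOSS",
                       c("chrom", "start", "end")], f_loss)
  stage_files$annotate <- c(f_ders, f_gain, f_loss)

  # -- integrate -----------------------------------------------------------
  out <- c(out, run_stage("integrate", {
    assignments <- assign_nearest_gene(ders, genes, expression,
                                       max_dist = config$max_dist)
    say(attr(assignments, "n_dropped"),
        " DER(s) beyond the distance gate were dropped")
    degs <- intersect_with_degs(assignments, expression)
    corr <- if (nrow(assignments) >= 3L) {
      pearson_fc_correlation(assignments)
    } else NULL
    wilcox <- lapply(c(GAIN = "GAIN", LOSS = "LOSS"), function(cl) {
      g <- degs[[cl]]
      e <- expression[match(g, expression$gene_id), , drop = FALSE]
      e <- e[complete.cases(e[, c("mean_ctrl", "mean_case")]), ,
             drop = FALSE]
      if (nrow(e) < 3L) return(NULL)
      wilcoxon_signed_rank(log2(e$mean_case + 1), log2(e$mean_ctrl + 1))
    })
    f_a <- file.path(out_dir, "assignments.tsv")
    data.table::fwrite(assignments, f_a, sep = "\t")
    stage_files$integrate <- f_a
    list(assignments = assignments, degs = degs, correlation = corr,
         wilcoxon = wilcox)
  }))

  # -- motifs --------------------------------------------------------------
  out <- c(out, run_stage("motifs", {
    gain_w <- summit_windows(ders[ders$class == "GAIN", , drop = FALSE],
                             assets, config$summit_halfwidth)
    loss_w <- summit_windows(ders[ders$class == "LOSS", , drop = FALSE],
                             assets, config$summit_halfwidth)
    non_der <- consensus[!consensus$region_id %in% ders$region_id, ,
                         drop = FALSE]
    bg_w <- summit_windows(non_der, assets, config$summit_halfwidth)
    enr_gain <- motif_enrichment(gain_w$seq, bg_w$seq, pwms,
                                 config$motif_threshold, config$motif_alpha)
    enr_loss <- motif_enrichment(loss_w$seq, bg_w$seq, pwms,
                                 config$motif_threshold, config$motif_alpha)
    detfs <- identify_detfs(enr_gain, enr_loss, expression,
                            alpha = config$motif_alpha)
    top <- pwms[[enr_gain$motif[1]]]
    occ <- occurrence_profile(top, ders[ders$class == "GAIN", , drop = FALSE],
                              assets, config$occ_halfwidth,
                              threshold_frac = config$motif_threshold)
    targets <- tf_targets(top, genes, expression, assets,
                          config$promoter_window, config$motif_threshold)
    f1 <- file.path(out_dir, "motif_enrichment_gain.tsv")
    f2 <- file.path(out_dir, "motif_enrichment_loss.tsv")
    f3 <- file.path(out_dir, "detfs.tsv")
    f4 <- file.path(out_dir, "occurrence_top_motif.tsv")
    f5 <- file.path(out_dir, "targets_top_motif.tsv")
    data.table::fwrite(enr_gain, f1, sep = "\t")
    data.table::fwrite(enr_loss, f2, sep = "\t")
    data.table::fwrite(detfs, f3, sep = "\t")
    data.table::fwrite(data.frame(offset = occ$breaks,
                                  density = occ$density), f4, sep = "\t")
    data.table::fwrite(targets, f5, sep = "\t")
    stage_files$motifs <- c(f1, f2, f3, f4, f5)
    list(motif_gain = enr_gain, motif_loss = enr_loss, detfs = detfs,
         occurrence = occ, targets = targets)
  }))

  # -- enrich --------------------------------------------------------------
  out <- c(out, run_stage("enrich", {
    res <- lapply(c(GAIN = "GAIN", LOSS = "LOSS"), function(cl) {
      q <- out$degs[[cl]]
      if (!length(q)) return(NULL)
      enrich_gene_sets(q, sets, expression, alpha = config$enrich_alpha,
                       fc_filter = config$fc_filter)
    })
    fns <- character(0)
    for (cl in names(res)) {
      if (is.null(res[[cl]])) next
      fn <- file.path(out_dir, paste0("pathways_", tolower(cl), ".tsv"))
      data.table::fwrite(res[[cl]], fn, sep = "\t")
      fns <- c(fns, fn)
    }
    stage_files$enrich <- fns
    list(enrichment_gain = res$GAIN, enrichment_loss = res$LOSS)
  }))

  # -- report --------------------------------------------------------------
  f_rep <- file.path(out_dir, "report.txt")
  run_stage("report", write_report(out, f_rep))
  stage_files$report <- f_rep

  manifest <- data.frame(
    stage = rep(names(stage_files), lengths(stage_files)),
    file = basename(unlist(stage_files, use.names = FALSE)),
    md5 = unname(tools::md5sum(unlist(stage_files, use.names = FALSE))),
    stringsAsFactors = FALSE)
  f_man <- file.path(out_dir, "manifest.tsv")
  params <- unclass(config)
  params$sim <- NULL; params$inputs <- NULL; params$groups <- NULL
  hdr <- c(paste0("# ", names(params), " = ",
                  vapply(params, function(v) paste(format(v), collapse = ","),
                         "")),
           if (!is.null(config$sim)) {
             paste0("# sim.", names(unclass(config$sim)), " = ",
                    vapply(unclass(config$sim), function(v)
                      paste(format(v, digits = 12), collapse = ","), ""))
           })
  writeLines(c(hdr, paste("stage", "file", "md5", sep = "\t"),
               paste(manifest$stage, manifest$file, manifest$md5,
                     sep = "\t")), f_man)
  out$manifest <- manifest
  say("pipeline complete in ",
      round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), " s")
  out
}

# plain-text report mirroring the figure panels as tables
write_report <- function(out, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  d <- out$ders
  w("== DER summary ==")
  w("GAIN regions: ", sum(d$class == "GAIN"),
    " | LOSS regions: ", sum(d$class == "LOSS"))
  w("")
  w("== Feature fractions (per class) ==")
  ft <- out$der_summary$features
  for (i in seq_len(nrow(ft))) {
    w(ft$class[i], "\t", ft$feature[i], "\t", sprintf("%.3f", ft$Freq[i]))
  }
  w("")
  w("== TSS-distance fractions (per class) ==")
  dt <- out$der_summary$distance
  for (i in seq_len(nrow(dt))) {
    w(dt$class[i], "\t", dt$bin[i], "\t", sprintf("%.3f", dt$Freq[i]))
  }
  w("")
  w("== DER-DEG integration ==")
  w("GAIN-linked DEGs: ", out$degs$counts[["GAIN"]],
    " | LOSS-linked DEGs: ", out$degs$counts[["LOSS"]])
  if (!is.null(out$correlation)) {
    w(sprintf("Pearson r (DER log2FC vs gene log2FC) = %.3f (n = %d, P = %.3g)",
              out$correlation$r, out$correlation$n, out$correlation$p))
  }
  for (cl in names(out$wilcoxon)) {
    ww <- out$wilcoxon[[cl]]
    if (!is.null(ww)) {
      w(sprintf("%s DEGs case-vs-ctrl signed-rank: W = %g, n = %d, P = %.3g",
                cl, ww$W, ww$n_eff, ww$p))
    }
  }
  w("")
  w("== Top motifs (GAIN windows) ==")
  mg <- head(out$motif_gain, 5L)
  for (i in seq_len(nrow(mg))) {
    w(sprintf("%s\tk=%d/%d\tbg=%d/%d\tP=%.3g", mg$motif[i], mg$k[i],
              mg$n[i], mg$k_bg[i], mg$n_bg[i], mg$p[i]))
  }
  w("")
  w("== Top pathways ==")
  for (cl in c("gain", "loss")) {
    e <- out[[paste0("enrichment_", cl)]]
    if (is.null(e) || !nrow(e)) next
    e <- head(e, 5L)
    for (i in seq_len(nrow(e))) {
      w(sprintf("%s\t%s\tk=%d/%d\tP=%.3g", toupper(cl), e$set[i], e$k[i],
                e$n[i], e$p[i]))
    }
  }
  invisible(path)
}
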