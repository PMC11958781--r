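#' Configuration for the synthetic study generator
#'
#' Defines a complete toy study emulating the statistical structure of a
#' two-condition CUT&Tag + RNA-seq experiment: a random genome with gene
#' models, consensus regions carrying negative-binomial fragment counts
#' with planted >2-fold GAIN/LOSS effects, an expression table whose gene
#' fold changes correlate with the planted region effects at a target
#' Pearson rho, motif instances planted preferentially in GAIN summit
#' windows, and one gene set enriched in GAIN-linked upregulated genes.
#'
#' @param seed master seed; every stage derives its own child stream from
#'   it, so stages are independently re-runnable.
#' @param n_chroms,chrom_length genome shape (total 1 Mb by default).
#' @param gc GC content of the simulated genome.
#' @param n_genes number of non-overlapping genes (alternating strands,
#'   2-5 exons each).
#' @param n_regions number of consensus regions (non-overlapping,
#'   quasi-uniformly tiled).
#' @param frac_gain,frac_loss fractions of regions planted as GAIN / LOSS;
#'   each planted region is placed so its nearest gene is unique.
#' @param effect_log2 range of |beta|, the planted log2 effect (the default
#'   lower bound log2(3) keeps every planted effect above the 2-fold call
#'   threshold with margin).
#' @param depth expected fragments per region per sample at baseline 1.
#' @param dispersion negative-binomial size parameter phi (variance =
#'   mu + mu^2/phi); \code{Inf} gives Poisson counts.
#' @param frip expected fraction of a library's fragments falling in
#'   consensus regions.  The remainder is genome-wide background placed in
#'   the inter-region gaps, a fixed library property shared by both
#'   conditions, emulating the background reads that dominate real
#'   library-size (RPKM) normalization; 0.3 is typical of a broadly
#'   distributed histone mark.  \code{frip = 1} disables background.
#' @param n_reps replicates per condition.
#' @param rho_target population Pearson correlation between planted region
#'   effects and their linked genes' log2 fold changes.
#' @param expr_noise_sd standard deviation (log2 units) of expression
#'   noise; 1.0 is typical of moderate biological noise in log2FC tables.
#' @param motif_consensus consensus of the planted motif (AP-1-like TGA
#'   core by default).
#' @param p_fg,p_bg probability of planting one motif instance in a GAIN
#'   summit window / a background (null-region) window.
#' @param motif_offset_sd sd (bp) of the planted-site offset from the
#'   summit.
#' @param n_gene_sets number of gene sets (one planted + decoys).
#' @param genes_per_set nominal set size.
#' @param planted_set_fraction fraction of the planted set drawn from
#'   GAIN-linked upregulated DEGs.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 500000L,
                       gc = 0.5, n_genes = 700L, n_regions = 2000L,
                       frac_gain = 0.1, frac_loss = 0.1,
                       effect_log2 = c(log2(3), 3), depth = 200,
                       dispersion = 10, frip = 0.3, n_reps = 2L,
                       rho_target = 0.7,
                       expr_noise_sd = 1.0,
                       motif_consensus = "TGACTCAGCA",
                       p_fg = 0.6, p_bg = 0.05, motif_offset_sd = 50,
                       n_gene_sets = 10L, genes_per_set = 30L,
                       planted_set_fraction = 0.6) {
  cfg <- as.list(environment())
  if (frac_gain < 0 || frac_loss < 0 || frac_gain + frac_loss > 1) {
    stop2("frac_gain + frac_loss must lie in [0, 1]")
  }
  if (!(p_bg >= 0 && p_bg <= p_fg && p_fg <= 1)) {
    stop2("need 0 <= p_bg <= p_fg <= 1")
  }
  if (abs(rho_target) > 1) stop2("rho_target must lie in [-1, 1]")
  if (dispersion <= 0) stop2("dispersion must be positive")
  if (length(effect_log2) != 2L || effect_log2[1] > effect_log2[2] ||
      effect_log2[1] <= 0) {
    stop2("effect_log2 must be an increasing positive range")
  }
  if (n_reps < 1L) stop2("need >= 1 replicate per condition")
  if (frip <= 0 || frip > 1) stop2("frip must lie in (0, 1]")
  if (gc <= 0 || gc >= 1) stop2("gc must lie in (0, 1)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_chroms, "x",
      x$chrom_length, "bp |", x$n_genes, "genes |", x$n_regions,
      "regions (", x$frac_gain, "GAIN /", x$frac_loss, "LOSS ) |",
      x$n_reps, "+", x$n_reps, "replicates | rho", x$rho_target, "\n")
  invisible(x)
}

#' Simulate a genome and gene models
#'
#' Bases are i.i.d. at the configured composition.  Genes are
#' non-overlapping, tiled with random lengths (400-900 bp) and gaps
#' (200-500 bp), on alternating strands, each with 2-5 exons whose first
#' and last coincide with the transcript ends.
#'
#' @param config \code{sim_config}.
#' @return list \code{assets} (\code{genome_assets}) and \code{genes}
#'   (gene-model data.frame).
#' @export
simulate_genome_and_genes <- function(config) {
  with_stage_seed(config$seed, "genome", {
    probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
               G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(BASES, config$chrom_length, TRUE, probs), collapse = "")
    }, "")
    names(seqs) <- paste0("chr", seq_len(config$n_chroms))
    assets <- genome_assets(
      setNames(rep(config$chrom_length, config$n_chroms), names(seqs)), seqs)
    need <- config$n_genes * 650 + 1000 * config$n_chroms
    have <- config$n_chroms * config$chrom_length
    if (config$n_genes > 0L && have < need) {
      stop2("genome too small for ", config$n_genes, " genes: need >= ",
            need, " bp, have ", have)
    }
    per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
    rows <- list()
    gid <- 0L
    for (ci in seq_len(config$n_chroms)) {
      cursor <- 500L
      for (k in seq_len(per[ci])) {
        len <- sample(400:900, 1L)
        if (cursor + len > config$chrom_length - 500L) {
          stop2("genome too small: could not place gene ", gid + 1L,
                " on chr", ci)
        }
        gid <- gid + 1L
        n_ex <- sample(2:5, 1L)
        w <- runif(2L * n_ex - 1L, 0.5, 1.5)
        sizes <- pmax(10L, as.integer(floor(w / sum(w) * len)))
        # exon/intron alternation; absorb rounding into the last exon
        bounds <- cumsum(c(0L, sizes))
        bounds[length(bounds)] <- len
        ex_s <- cursor + bounds[seq(1L, 2L * n_ex - 1L, by = 2L)]
        ex_e <- cursor + bounds[seq(2L, 2L * n_ex, by = 2L)]
        ex_e[n_ex] <- cursor + len
        rows[[gid]] <- data.frame(
          gene_id = sprintf("gene_%04d", gid), chrom = paste0("chr", ci),
          strand = if (gid %% 2L == 1L) "+" else "-",
          tx_start = cursor, tx_end = cursor + len,
          exon_starts = paste(ex_s, collapse = ","),
          exon_ends = paste(ex_e, collapse = ","), stringsAsFactors = FALSE)
        cursor <- cursor + len + sample(200:500, 1L)
      }
    }
    genes <- if (gid) do.call(rbind, rows) else
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), tx_start = integer(),
                 tx_end = integer(), exon_starts = character(),
                 exon_ends = character(), stringsAsFactors = FALSE)
    genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
    genes$tes <- ifelse(genes$strand == "+", genes$tx_end - 1L, genes$tx_start)
    genes <- genes[, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                       "tss", "tes", "exon_starts", "exon_ends")]
    list(assets = assets, genes = genes)
  })
}

#' Simulate consensus regions and replicate fragment signal
#'
#' Regions are tiled quasi-uniformly (one per stride cell, so they never
#' overlap).  GAIN/LOSS classes are planted on regions chosen so that each
#' planted region's nearest gene is unique, guaranteeing the nearest-gene
#' step has recoverable signal.  Per region r and sample s in condition c,
#' the fragment count is NegBin(mean = depth * u_r * 2^(beta_r [c=case]),
#' size = phi) with baseline u_r ~ LogNormal(0, 0.5); fragments are placed
#' uniformly within the region.  The summit is recorded at the region
#' midpoint.
#'
#' @param config \code{sim_config}.
#' @param genes gene models from \code{\link{simulate_genome_and_genes}}.
#' @return list \code{regions} (with \code{region_id} and \code{summit}),
#'   \code{samples} (named list of fragment data.frames, ctrl_* then
#'   case_*), \code{groups}, and \code{truth} (per-region class, beta,
#'   baseline, linked gene and TSS distance).
#' @export
simulate_signal <- function(config, genes) {
  with_stage_seed(config$seed, "signal", {
    per <- diff(round(seq(0, config$n_regions,
                          length.out = config$n_chroms + 1)))
    regs <- list()
    for (ci in seq_len(config$n_chroms)) {
      if (per[ci] == 0L) next
      stride <- config$chrom_length / per[ci]
      if (stride < 60) stop2("too many regions for the genome")
      wmax <- as.integer(min(400, stride - 10))
      w <- sample(200:max(200L, wmax), per[ci], TRUE)
      w <- pmin(w, wmax)
      s0 <- as.integer(floor((seq_len(per[ci]) - 1L) * stride +
                             runif(per[ci], 0, stride - w)))
      regs[[ci]] <- data.frame(chrom = paste0("chr", ci), start = s0,
                               end = s0 + w, stringsAsFactors = FALSE)
    }
    regions <- do.call(rbind, regs)
    regions$region_id <- sprintf("region_%05d", seq_len(nrow(regions)))
    regions$summit <- interval_midpoint(regions)
    # nearest gene per region (for planting with unique linkage)
    nn <- assign_nearest_gene(
      data.frame(region_id = regions$region_id, chrom = regions$chrom,
                 start = regions$start, end = regions$end,
                 stringsAsFactors = FALSE),
      genes, max_dist = 100000L)
    n_gain <- round(config$frac_gain * nrow(regions))
    n_loss <- round(config$frac_loss * nrow(regions))
    cls <- rep("null", nrow(regions))
    beta <- numeric(nrow(regions))
    linked <- rep(NA_character_, nrow(regions))
    if (n_gain + n_loss > 0L) {
      cand <- nn[sample.int(nrow(nn)), , drop = FALSE]
      cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
      if (nrow(cand) < n_gain + n_loss) {
        stop2("not enough genes with unique nearest regions to plant ",
              n_gain + n_loss, " effects (have ", nrow(cand), ")")
      }
      sel <- match(cand$region_id[seq_len(n_gain + n_loss)],
                   regions$region_id)
      cls[sel] <- rep(c("GAIN", "LOSS"), c(n_gain, n_loss))
      mag <- runif(n_gain + n_loss, config$effect_log2[1],
                   config$effect_log2[2])
      beta[sel] <- mag * ifelse(cls[sel] == "GAIN", 1, -1)
      linked[sel] <- cand$gene_id[seq_len(n_gain + n_loss)]
    }
    u <- rlnorm(nrow(regions), 0, 0.5)
    # inter-region gaps able to host a whole 100 bp background fragment;
    # background never overlaps a region, so region counts stay exact
    gaps <- do.call(rbind, lapply(paste0("chr", seq_len(config$n_chroms)),
                                  function(ch) {
      r <- regions[regions$chrom == ch, , drop = FALSE]
      bnd <- c(0L, as.vector(rbind(r$start, r$end)), config$chrom_length)
      gs <- bnd[seq(1L, length(bnd), by = 2L)]
      ge <- bnd[seq(2L, length(bnd), by = 2L)]
      data.frame(chrom = ch, start = gs, end = ge,
                 stringsAsFactors = FALSE)
    }))
    gaps$avail <- gaps$end - gaps$start - 100L + 1L
    gaps <- gaps[gaps$avail > 0L, , drop = FALSE]
    bg_mean <- config$depth * sum(u) * (1 - config$frip) / config$frip
    samples <- list()
    groups <- character(0)
    for (grp in c("ctrl", "case")) {
      for (rep_i in seq_len(config$n_reps)) {
        mu <- config$depth * u * if (grp == "case") 2^beta else 1
        cnt <- if (is.infinite(config$dispersion)) {
          stats::rpois(length(mu), mu)
        } else {
          rnbinom(length(mu), mu = mu, size = config$dispersion)
        }
        width <- regions$end - regions$start
        flen <- pmin(100L, width)
        ri <- rep(seq_len(nrow(regions)), cnt)
        fs <- regions$start[ri] +
          as.integer(floor(runif(length(ri), 0, (width - flen + 1L)[ri])))
        nm <- paste0(grp, "_", rep_i)
        fr <- data.frame(chrom = regions$chrom[ri], start = fs,
                         end = fs + flen[ri], stringsAsFactors = FALSE)
        if (config$frip < 1 && nrow(gaps)) {
          n_bg <- stats::rpois(1L, bg_mean)
          gi <- sample.int(nrow(gaps), n_bg, TRUE, prob = gaps$avail)
          bs <- gaps$start[gi] +
            as.integer(floor(runif(n_bg, 0, gaps$avail[gi])))
          fr <- rbind(fr, data.frame(chrom = gaps$chrom[gi], start = bs,
                                     end = bs + 100L,
                                     stringsAsFactors = FALSE))
        }
        samples[[nm]] <- fr
        groups[nm] <- grp
      }
    }
    truth <- data.frame(region_id = regions$region_id, class = cls,
                        beta = beta, baseline = u, linked_gene = linked,
                        dist_tss = nn$distance[match(regions$region_id,
                                                     nn$region_id)],
                        stringsAsFactors = FALSE)
    list(regions = regions[, c("region_id", "chrom", "start", "end",
                               "summit")],
         samples = samples, groups = groups, truth = truth)
  })
}

#' Simulate an expression table correlated with planted region effects
#'
#' Linked genes receive \code{log2fc = a * beta + e},
#' \code{e ~ Normal(0, expr_noise_sd)}, with \code{a} chosen from the
#' planted-beta spread so the population Pearson correlation between beta
#' and log2fc equals \code{rho_target}; unlinked genes receive pure noise.
#' Group means are LogNormal baselines consistent with the fold change,
#' and \code{significant} applies the downstream DEG filter |log2fc| > 1.
#'
#' @param config \code{sim_config}.
#' @param truth region truth table from \code{\link{simulate_signal}}.
#' @param genes gene models.
#' @return list \code{expression} (table as read by
#'   \code{\link{read_expression_table}}) and \code{truth_genes}
#'   (per-gene planted log2fc, DEG flag, linked region).
#' @export
simulate_expression <- function(config, truth, genes) {
  with_stage_seed(config$seed, "expression", {
    rho <- config$rho_target
    se <- config$expr_noise_sd
    planted <- truth[truth$class != "null" & !is.na(truth$linked_gene), ,
                     drop = FALSE]
    if (abs(rho) == 1) {
      if (se != 0) {
        stop2("rho_target of +/-1 requires expr_noise_sd = 0")
      }
      a <- sign(rho)
    } else {
      if (se == 0) {
        stop2("rho_target ", rho, " is incompatible with expr_noise_sd = 0",
              " (noiseless linkage is perfectly correlated)")
      }
      sb <- if (nrow(planted) > 1L) sd(planted$beta) else 1
      a <- rho * se / (sb * sqrt(1 - rho^2))
    }
    fc <- rnorm(nrow(genes), 0, se)
    i <- match(genes$gene_id, planted$linked_gene)
    hit <- !is.na(i)
    fc[hit] <- a * planted$beta[i[hit]] +
      if (se > 0) rnorm(sum(hit), 0, se) else 0
    base <- rlnorm(nrow(genes), log(10), 1)
    expr <- data.frame(gene_id = genes$gene_id, mean_ctrl = base,
                       mean_case = base * 2^fc, log2fc = fc,
                       significant = abs(fc) > 1, stringsAsFactors = FALSE)
    truth_genes <- data.frame(
      gene_id = genes$gene_id, planted_log2fc = fc, deg = abs(fc) > 1,
      linked_region = ifelse(hit, planted$region_id[i], NA_character_),
      linked_class = ifelse(hit, planted$class[i], NA_character_),
      stringsAsFactors = FALSE)
    list(expression = expr, truth_genes = truth_genes)
  })
}

# sample one site sequence from a PWM's raw base frequencies (a consensus
# motif therefore always emits its consensus)
sample_site <- function(motif) {
  paste(vapply(seq_len(motif$length), function(i) {
    sample(BASES, 1L, prob = motif$freq[i, ])
  }, ""), collapse = "")
}

#' Plant motif instances into summit windows
#'
#' With probability \code{p_fg} (foreground windows) or \code{p_bg}
#' (background windows) one site sampled from the PWM is written into the
#' genome at an offset ~ Normal(0, \code{offset_sd}) from the window
#' center, clipped so the site stays inside the window.
#'
#' @param config \code{sim_config} (supplies p_fg, p_bg, offset sd and the
#'   consensus unless \code{motif} is given).
#' @param windows window table from \code{\link{summit_windows}} with a
#'   logical \code{foreground} column.
#' @param assets \code{genome_assets} with sequence (modified copy is
#'   returned).
#' @param motif optional \code{pwm}; defaults to the config consensus.
#' @return list \code{assets} (modified), \code{truth_motifs}
#'   (window_id, planted flag, offset of the site center from the summit).
#' @export
plant_motifs <- function(config, windows, assets, motif = NULL) {
  motif <- motif %||% pwm_from_consensus(config$motif_consensus,
                                         name = "planted_motif")
  L <- motif$length
  if (any(windows$end - windows$start < L)) {
    stop2("motif longer than a window")
  }
  with_stage_seed(config$seed, "motifs", {
    p <- ifelse(windows$foreground, config$p_fg, config$p_bg)
    plant <- runif(nrow(windows)) < p
    offs <- rep(NA_integer_, nrow(windows))
    seqs <- as.character(assets$seq)
    for (i in which(plant)) {
      off <- as.integer(round(rnorm(1, 0, config$motif_offset_sd)))
      center <- windows$summit[i] + off
      s <- center - L %/% 2L
      s <- max(windows$start[i], min(s, windows$end[i] - L))
      site <- sample_site(motif)
      ch <- windows$chrom[i]
      substr(seqs[[ch]], s + 1L, s + L) <- site
      offs[i] <- s + L %/% 2L - windows$summit[i]
    }
    assets <- genome_assets(assets$chrom_sizes, seqs)
    list(assets = assets,
         truth_motifs = data.frame(window_id = windows$window_id,
                                   planted = plant, offset = offs,
                                   stringsAsFactors = FALSE))
  })
}

#' Random decoy PWMs
#'
#' @param config \code{sim_config} (seed source).
#' @param n number of decoys.
#' @param length motif length.
#' @return named list of \code{pwm} objects built from random consensus
#'   sequences.
#' @export
decoy_pwms <- function(config, n, length = NULL) {
  length <- length %||% nchar(config$motif_consensus)
  with_stage_seed(config$seed, "decoys", {
    out <- lapply(seq_len(n), function(i) {
      pwm_from_consensus(paste(sample(BASES, length, TRUE), collapse = ""),
                         name = sprintf("decoy_%03d", i))
    })
    names(out) <- vapply(out, `[[`, "", "name")
    out
  })
}

#' Simulate gene sets with one planted enriched set
#'
#' Decoy sets are uniform draws from the gene universe; the planted set
#' draws \code{planted_set_fraction} of its members from GAIN-linked
#' upregulated DEGs (falling back to random genes if there are too few).
#'
#' @param config \code{sim_config}.
#' @param truth_genes gene truth from \code{\link{simulate_expression}}.
#' @return list \code{sets} (GMT-style list; the planted set is named
#'   \code{"planted_set"}) and \code{planted_set} (its name).
#' @export
simulate_gene_sets <- function(config, truth_genes) {
  with_stage_seed(config$seed, "genesets", {
    universe <- truth_genes$gene_id
    k <- min(config$genes_per_set, length(universe))
    sets <- lapply(seq_len(max(config$n_gene_sets - 1L, 0L)), function(i) {
      sample(universe, k)
    })
    names(sets) <- sprintf("decoy_set_%02d", seq_along(sets))
    target <- truth_genes$gene_id[
      truth_genes$deg & truth_genes$planted_log2fc > 0 &
      truth_genes$linked_class %in% "GAIN"]
    n_in <- min(length(target), round(config$planted_set_fraction * k))
    members <- sample(target, n_in)
    filler <- sample(setdiff(universe, members), k - n_in)
    sets$planted_set <- c(members, filler)
    attr(sets, "description") <- setNames(
      c(rep("decoy pathway", length(sets) - 1L), "planted pathway"),
      names(sets))
    list(sets = sets, planted_set = "planted_set")
  })
}

#' Run the full synthetic study and (optionally) write its files
#'
#' Orchestrates genome, signal, expression, motif planting (GAIN summit
#' windows are foreground; null-region windows are background) and gene
#' sets.  With \code{dir} set, emits genome.fa, genes.bed,
#' peaks_<sample>.bed, consensus.bed, fragments_<sample>.bed,
#' expression.tsv, sets.gmt, motifs.pfm, truth_regions.tsv,
#' truth_genes.tsv, truth_motifs.tsv and config.txt.
#'
#' @param config \code{sim_config}.
#' @param dir optional output directory (created if missing).
#' @param n_decoy_pwms decoy motifs written alongside the planted one.
#' @param motif_halfwidth summit-window halfwidth used for planting.
#' @return list with all in-memory pieces: \code{config, assets, genes,
#'   regions, samples, groups, expression, sets, pwms, truth} (regions /
#'   genes / motifs tables), \code{files} (when written).
#' @export
simulate_study <- function(config, dir = NULL, n_decoy_pwms = 10L,
                           motif_halfwidth = 200L) {
  gg <- simulate_genome_and_genes(config)
  sig <- simulate_signal(config, gg$genes)
  ex <- simulate_expression(config, sig$truth, gg$genes)
  win <- summit_windows(sig$regions, gg$assets, motif_halfwidth)
  win$foreground <- sig$truth$class[match(win$window_id,
                                          sig$truth$region_id)] == "GAIN"
  pm <- plant_motifs(config, win, gg$assets)
  planted <- pwm_from_consensus(config$motif_consensus, name = "planted_motif")
  pwms <- c(list(planted_motif = planted), decoy_pwms(config, n_decoy_pwms))
  gs <- simulate_gene_sets(config, ex$truth_genes)
  out <- list(config = config, assets = pm$assets, genes = gg$genes,
              regions = sig$regions, samples = sig$samples,
              groups = sig$groups, expression = ex$expression,
              sets = gs$sets, pwms = pwms,
              truth = list(regions = sig$truth, genes = ex$truth_genes,
                           motifs = pm$truth_motifs,
                           planted_set = gs$planted_set))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(...) file.path(dir, paste0(...))
    write_fasta(pm$assets, f("genome.fa"))
    write_gene_models(gg$genes, f("genes.bed"))
    write_intervals(sig$regions[, c("chrom", "start", "end")],
                    f("consensus.bed"))
    for (s in names(sig$samples)) {
      write_intervals(sig$regions[, c("chrom", "start", "end")],
                      f("peaks_", s, ".bed"))
      write_intervals(sig$samples[[s]], f("fragments_", s, ".bed"))
    }
    write_expression_table(ex$expression, f("expression.tsv"))
    write_gene_sets(gs$sets, f("sets.gmt"))
    write_pfm(pwms, f("motifs.pfm"))
    data.table::fwrite(sig$truth, f("truth_regions.tsv"), sep = "\t")
    data.table::fwrite(ex$truth_genes, f("truth_genes.tsv"), sep = "\t")
    data.table::fwrite(pm$truth_motifs, f("truth_motifs.tsv"), sep = "\t")
    writeLines(paste(names(unclass(config)),
                     vapply(unclass(config), function(v)
                       paste(format(v, digits = 12), collapse = ","), ""),
                     sep = "="), f("config.txt"))
    out$files <- list.files(dir, full.names = TRUE)
  }
  out
}
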