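#' Build consensus regions from per-sample peak sets
#'
#' Consensus = union of all samples' peaks, merged with \code{gap = 0}
#' (book-ended peaks join).  Each consensus region records which samples
#' contributed at least one overlapping peak.
#'
#' @param peak_list named list of peak data.frames (from
#'   \code{\link{read_intervals}}).
#' @return data.frame \code{region_id, chrom, start, end, samples}.
#' @export
build_consensus <- function(peak_list) {
  stopifnot(is.list(peak_list), length(peak_list) >= 1L)
  all_peaks <- do.call(rbind, lapply(peak_list, function(p) {
    p[, c("chrom", "start", "end")]
  }))
  if (is.null(all_peaks) || nrow(all_peaks) == 0L) stop2("no peaks")
  cons <- merge_intervals(all_peaks, gap = 0L)
  cons$region_id <- sprintf("region_%05d", seq_len(nrow(cons)))
  nm <- names(peak_list) %||% paste0("sample", seq_along(peak_list))
  contrib <- matrix(FALSE, nrow(cons), length(peak_list))
  for (j in seq_along(peak_list)) {
    contrib[, j] <- count_overlapping_fragments(cons, peak_list[[j]]) > 0L
  }
  cons$samples <- apply(contrib, 1, function(z) paste(nm[z], collapse = ","))
  cons[, c("region_id", "chrom", "start", "end", "samples")]
}

#' Quantify consensus regions per sample as RPKM
#'
#' In \code{fragments} mode each sample is a fragment interval set; the
#' library size is its total fragment count and
#' \deqn{RPKM = count \times 10^9 / (length_{bp} \times library)}
#' In \code{track} mode each sample is an RPKM-normalized bedGraph and the
#' region value is the mean of the track over the region's bases (missing
#' bases read 0).
#'
#' @param consensus consensus regions from \code{\link{build_consensus}}
#'   (any interval data.frame with a \code{region_id} column works).
#' @param samples named list; per sample either a data.frame (fragments or
#'   bedgraph, per \code{mode}) or a file path to one.
#' @param groups named character vector mapping sample name to
#'   \code{"ctrl"} or \code{"case"}.
#' @param mode \code{"fragments"} or \code{"track"}.
#' @return object of class \code{rpkm_matrix}: list with \code{rpkm}
#'   (regions x samples), \code{counts} (fragments mode), per-sample
#'   \code{library_sizes}, \code{groups} and the \code{regions} table.
#' @export
quantify_regions <- function(consensus, samples, groups,
                             mode = c("fragments", "track")) {
  mode <- match.arg(mode)
  nm <- names(samples)
  if (is.null(nm)) stop2("samples must be a named list")
  if (!all(nm %in% names(groups))) stop2("every sample needs a group")
  if (!all(groups[nm] %in% c("ctrl", "case"))) {
    stop2("groups must be 'ctrl' or 'case'")
  }
  nr <- nrow(consensus)
  len <- consensus$end - consensus$start
  rpkm <- matrix(0, nr, length(samples), dimnames = list(consensus$region_id, nm))
  counts <- NULL
  libs <- setNames(numeric(length(samples)), nm)
  if (mode == "fragments") {
    counts <- rpkm
    for (s in nm) {
      fr <- samples[[s]]
      if (is.character(fr)) fr <- read_intervals(fr, "fragments")
      libs[s] <- nrow(fr)
      if (libs[s] == 0) stop2("sample ", s, ": library size is zero")
      counts[, s] <- count_overlapping_fragments(consensus, fr)
      rpkm[, s] <- counts[, s] * 1e9 / (len * libs[s])
    }
  } else {
    for (s in nm) {
      tr <- samples[[s]]
      if (is.character(tr)) tr <- read_intervals(tr, "bedgraph")
      libs[s] <- NA_real_
      rpkm[, s] <- track_region_means(tr, consensus)
    }
  }
  structure(list(rpkm = rpkm, counts = counts, library_sizes = libs,
                 groups = groups[nm], regions = consensus, mode = mode),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat("rpkm_matrix:", nrow(x$rpkm), "regions x", ncol(x$rpkm), "samples (",
      sum(x$groups == "ctrl"), "ctrl /", sum(x$groups == "case"), "case ),",
      x$mode, "mode\n")
  invisible(x)
}

# mean bedgraph value over each region's bases (uncovered bases = 0)
track_region_means <- function(track, regions) {
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0L) next
    # coverage-weighted sum via interval intersection
    ir_t <- iranges_of(tr)
    ir_r <- iranges_of(regions[ri, , drop = FALSE])
    ov <- IRanges::findOverlaps(ir_r, ir_t)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    w <- pmin(IRanges::end(ir_r)[qi], IRanges::end(ir_t)[si]) -
      pmax(IRanges::start(ir_r)[qi], IRanges::start(ir_t)[si]) + 1L
    sums <- tapply(w * tr$value[si], qi, sum)
    out[ri[as.integer(names(sums))]] <-
      sums / (regions$end[ri] - regions$start[ri])[as.integer(names(sums))]
  }
  out
}

#' Call differentially enriched regions (DERs) by the fold rule
#'
#' Group means are arithmetic means of replicate RPKMs.  A region is GAIN
#' when \code{(mean_case + eps) / (mean_ctrl + eps) > fold} and LOSS when
#' the inverse ratio exceeds \code{fold}; everything else is not a DER.
#' The pseudocount \code{eps} (RPKM units) stabilizes zero-signal regions,
#' which would otherwise be infinite-fold calls.
#'
#' @param mat \code{rpkm_matrix} from \code{\link{quantify_regions}}.
#' @param fold fold-change threshold (> 1); the study rule is "> 2-fold".
#' @param eps pseudocount in RPKM units added to both group means.
#' @return data.frame of DERs sorted by decreasing |log2fc| within class
#'   (GAIN block first): \code{region_id, chrom, start, end, summit, class,
#'   mean_ctrl, mean_case, log2fc}.  \code{summit} is the region midpoint.
#' @export
call_ders <- function(mat, fold = 2, eps = 0.5) {
  stopifnot(inherits(mat, "rpkm_matrix"))
  if (fold <= 1) stop2("fold threshold must exceed 1")
  if (eps < 0) stop2("pseudocount must be non-negative")
  ci <- which(mat$groups == "ctrl"); ca <- which(mat$groups == "case")
  if (!length(ci) || !length(ca)) stop2("need >= 1 sample in each group")
  mean_ctrl <- rowMeans(mat$rpkm[, ci, drop = FALSE])
  mean_case <- rowMeans(mat$rpkm[, ca, drop = FALSE])
  ratio <- (mean_case + eps) / (mean_ctrl + eps)
  cls <- ifelse(ratio > fold, "GAIN", ifelse(1 / ratio > fold, "LOSS", NA))
  keep <- which(!is.na(cls))
  reg <- mat$regions[keep, , drop = FALSE]
  out <- data.frame(region_id = reg$region_id, chrom = reg$chrom,
                    start = reg$start, end = reg$end,
                    summit = interval_midpoint(reg),
                    class = cls[keep],
                    mean_ctrl = mean_ctrl[keep], mean_case = mean_case[keep],
                    log2fc = log2(ratio[keep]), stringsAsFactors = FALSE)
  out <- out[order(out$class, -abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate regions by genomic feature and distance to nearest TSS
#'
#' The region midpoint drives annotation, with precedence promoter-TSS >
#' TES > exon > intron > intergenic.  The promoter window is
#' \code{[TSS - promoter_upstream, TSS + promoter_downstream)} in
#' strand-oriented coordinates; TES means within \code{tes_margin} bp of a
#' transcription end site.  The signed TSS distance is strand-oriented
#' (negative = upstream of the nearest TSS).
#'
#' @param regions intervals data.frame (e.g. DERs).
#' @param genes gene models from \code{\link{read_gene_models}}.
#' @param promoter_upstream,promoter_downstream promoter window bounds (bp).
#' @param tes_margin TES proximity margin (bp).
#' @return \code{regions} with added columns \code{feature},
#'   \code{nearest_gene} and \code{dist_tss} (Inf when no gene exists).
#' @export
annotate_feature <- function(regions, genes, promoter_upstream = 1000L,
                             promoter_downstream = 100L, tes_margin = 100L) {
  n <- nrow(regions)
  regions$feature <- rep("intergenic", n)
  regions$nearest_gene <- rep(NA_character_, n)
  regions$dist_tss <- rep(Inf, n)
  if (n == 0L || nrow(genes) == 0L) return(regions)
  mid <- interval_midpoint(regions)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    m <- mid[ri]
    # nearest TSS (ties to the lexicographically smallest gene_id)
    o <- order(g$tss, g$gene_id)
    g <- g[o, , drop = FALSE]
    pos <- findInterval(m, g$tss)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, nrow(g))
    d_lo <- abs(m - g$tss[lo]); d_hi <- abs(m - g$tss[hi])
    pick_hi <- d_hi < d_lo |
      (d_hi == d_lo & g$gene_id[hi] < g$gene_id[lo])
    ng <- ifelse(pick_hi, hi, lo)
    gsel <- g[ng, , drop = FALSE]
    signed <- ifelse(gsel$strand == "+", m - gsel$tss, gsel$tss - m)
    regions$nearest_gene[ri] <- gsel$gene_id
    regions$dist_tss[ri] <- signed
    # feature precedence over *all* genes on the chromosome
    pt <- IRanges::IRanges(start = m + 1L, width = 1L)
    prom <- IRanges::IRanges(
      start = ifelse(g$strand == "+", g$tss - promoter_upstream,
                     g$tss - promoter_downstream + 1L) + 1L,
      end = ifelse(g$strand == "+", g$tss + promoter_downstream,
                   g$tss + promoter_upstream))
    in_prom <- IRanges::overlapsAny(pt, prom)
    tesr <- IRanges::IRanges(start = g$tes - tes_margin + 1L,
                             end = g$tes + tes_margin + 1L)
    in_tes <- IRanges::overlapsAny(pt, tesr)
    body <- IRanges::IRanges(start = g$tx_start + 1L, end = g$tx_end)
    in_body <- IRanges::overlapsAny(pt, body)
    ex_st <- as.integer(unlist(strsplit(g$exon_starts, ",")))
    ex_en <- as.integer(unlist(strsplit(g$exon_ends, ",")))
    in_exon <- IRanges::overlapsAny(
      pt, IRanges::IRanges(start = ex_st + 1L, end = ex_en))
    feat <- ifelse(in_prom, "promoter-TSS",
            ifelse(in_tes, "TES",
            ifelse(in_body & in_exon, "exon",
            ifelse(in_body, "intron", "intergenic"))))
    regions$feature[ri] <- feat
  }
  regions
}

#' Summarize annotated DERs by TSS distance and chromosome
#'
#' @param ders annotated DERs (output of \code{\link{annotate_feature}} on
#'   \code{\link{call_ders}} output, with a \code{class} column).
#' @return list with \code{distance} (per class, fractions of |distance to
#'   TSS| in 0-1 kb, 1-10 kb, 10-100 kb, >100 kb), \code{chromosomes}
#'   (per-class counts) and \code{features} (per-class feature fractions).
#' @export
distance_summary <- function(ders) {
  if (nrow(ders) == 0L) {
    return(list(distance = data.frame(), chromosomes = data.frame(),
                features = data.frame()))
  }
  d <- abs(ders$dist_tss)
  bin <- cut(d, c(-1, 1000, 10000, 100000, Inf),
             labels = c("0-1kb", "1-10kb", "10-100kb", ">100kb"))
  dist_tab <- as.data.frame(prop.table(table(class = ders$class, bin = bin),
                                       margin = 1))
  chrom_tab <- as.data.frame(table(class = ders$class, chrom = ders$chrom))
  feat_tab <- as.data.frame(prop.table(
    table(class = ders$class, feature = ders$feature), margin = 1))
  list(distance = dist_tab, chromosomes = chrom_tab, features = feat_tab)
}

# per-chromosome dense value vector from a bedgraph data.frame
track_vector <- function(track, chrom, chrom_len) {
  v <- numeric(chrom_len)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      s <- max(tr$start[i], 0L); e <- min(tr$end[i], chrom_len)
      if (s < e) v[(s + 1L):e] <- tr$value[i]
    }
  }
  v
}

profile_slice <- function(v, start, end) {
  # mean of v over 0-based [start, end), positions off-chromosome read 0
  n <- end - start
  if (n <= 0L) return(NA_real_)
  lo <- max(start, 0L); hi <- min(end, length(v))
  if (lo >= hi) return(0)
  sum(v[(lo + 1L):hi]) / n
}

#' Scaled meta-gene profile of a signal track
#'
#' Averages track signal over all genes in a strand-oriented frame: a fixed
#' upstream flank before the TSS, the gene body linearly rescaled to
#' \code{body_bins} bins, and a fixed downstream flank after the TES.
#' Genes shorter than \code{body_bins} bp are skipped (counted).
#'
#' @param track bedgraph data.frame.
#' @param genes gene models.
#' @param assets \code{genome_assets} (for chromosome lengths).
#' @param upstream,downstream flank sizes in bp.
#' @param body_bins number of scaled gene-body bins.
#' @param bin flank bin width in bp.
#' @return object of class \code{meta_profile}: \code{values} per bin,
#'   \code{section} labels (upstream/body/downstream), \code{n_genes},
#'   \code{n_skipped}.
#' @export
meta_profile <- function(track, genes, assets, upstream = 2000L,
                         downstream = 2000L, body_bins = 100L, bin = 20L) {
  nb_up <- upstream %/% bin; nb_dn <- downstream %/% bin
  total <- nb_up + body_bins + nb_dn
  acc <- numeric(total); used <- 0L; skipped <- 0L
  vs <- lapply(setNames(nm = unique(genes$chrom)), function(ch) {
    track_vector(track, ch, assets$chrom_sizes[[ch]])
  })
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$tx_end - g$tx_start
    if (len < body_bins) { skipped <- skipped + 1L; next }
    v <- vs[[g$chrom]]
    fwd <- g$strand == "+"
    up <- vapply(seq_len(nb_up), function(b) {
      if (fwd) profile_slice(v, g$tx_start - upstream + (b - 1L) * bin,
                             g$tx_start - upstream + b * bin)
      else profile_slice(v, g$tx_end + upstream - b * bin,
                         g$tx_end + upstream - (b - 1L) * bin)
    }, 0)
    edges <- g$tx_start + floor(seq(0L, len, length.out = body_bins + 1L))
    body <- vapply(seq_len(body_bins), function(b) {
      profile_slice(v, edges[b], max(edges[b + 1L], edges[b] + 1L))
    }, 0)
    if (!fwd) body <- base::rev(body)
    dn <- vapply(seq_len(nb_dn), function(b) {
      if (fwd) profile_slice(v, g$tx_end + (b - 1L) * bin, g$tx_end + b * bin)
      else profile_slice(v, g$tx_start - b * bin, g$tx_start - (b - 1L) * bin)
    }, 0)
    acc <- acc + c(up, body, dn)
    used <- used + 1L
  }
  structure(list(values = if (used) acc / used else acc,
                 section = rep(c("upstream", "body", "downstream"),
                               c(nb_up, body_bins, nb_dn)),
                 bin = bin, n_genes = used, n_skipped = skipped),
            class = "meta_profile")
}

#' Signal profile centered on DER midpoints
#'
#' @param track bedgraph data.frame.
#' @param ders DER table (uses \code{summit} when present, midpoint
#'   otherwise).
#' @param assets \code{genome_assets}.
#' @param flank half-window in bp around each center.
#' @param bin bin width in bp.
#' @return \code{meta_profile} whose bins tile \code{[-flank, +flank)};
#'   \code{position} holds each bin's left edge relative to the center.
#' @export
der_center_profile <- function(track, ders, assets, flank = 2000L, bin = 20L) {
  nb <- (2L * flank) %/% bin
  acc <- numeric(nb)
  centers <- if ("summit" %in% names(ders) && !anyNA(ders$summit)) {
    ders$summit
  } else interval_midpoint(ders)
  vs <- lapply(setNames(nm = unique(ders$chrom)), function(ch) {
    track_vector(track, ch, assets$chrom_sizes[[ch]])
  })
  for (i in seq_len(nrow(ders))) {
    v <- vs[[ders$chrom[i]]]
    c0 <- centers[i]
    acc <- acc + vapply(seq_len(nb), function(b) {
      profile_slice(v, c0 - flank + (b - 1L) * bin, c0 - flank + b * bin)
    }, 0)
  }
  structure(list(values = if (nrow(ders)) acc / nrow(ders) else acc,
                 position = seq(-flank, flank - bin, by = bin),
                 section = rep("center", nb), bin = bin,
                 n_genes = nrow(ders), n_skipped = 0L),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", length(x$values), "bins of", x$bin, "bp,",
      x$n_genes, "features averaged",
      if (x$n_skipped) paste0("(", x$n_skipped, " skipped)") else "", "\n")
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "l",
                 xlab = "bin", ylab = "mean signal", ...)
  invisible(x)
}
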