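#' Extract sequence windows around region summits
#'
#' Windows span \code{[summit - halfwidth, summit + halfwidth)}; when a
#' region has no summit its midpoint is used.  Windows running off a
#' chromosome end are clipped (their realized span is recorded); windows
#' entirely off-chromosome are skipped.
#'
#' @param regions region/DER table (needs \code{chrom,start,end}; uses
#'   \code{summit} when present).
#' @param assets \code{genome_assets} with sequence.
#' @param halfwidth half window size in bp (the study convention is
#'   \code{-200,200} around summits).
#' @return data.frame \code{window_id, chrom, start, end, summit, seq};
#'   \code{window_id} echoes \code{region_id} when available.
#' @export
summit_windows <- function(regions, assets, halfwidth = 200L) {
  n <- nrow(regions)
  centers <- if ("summit" %in% names(regions) && !anyNA(regions$summit)) {
    regions$summit
  } else interval_midpoint(regions)
  ids <- regions$region_id %||% sprintf("window_%05d", seq_len(n))
  out <- data.frame(window_id = ids, chrom = regions$chrom,
                    start = pmax(centers - halfwidth, 0L),
                    end = centers + halfwidth, summit = centers,
                    stringsAsFactors = FALSE)
  out$end <- pmin(out$end, unname(assets$chrom_sizes[out$chrom]))
  ok <- out$start < out$end
  if (any(!ok)) {
    warning(sum(!ok), " window(s) entirely off-chromosome were skipped")
  }
  out <- out[ok, , drop = FALSE]
  out$seq <- vapply(seq_len(nrow(out)), function(i) {
    fetch_sequence(assets, out$chrom[i], out$start[i], out$end[i], "+")
  }, "")
  rownames(out) <- NULL
  out
}

#' Motif enrichment of target windows against a background
#'
#' For each PWM the fraction of target windows with at least one hit is
#' tested against the background hit fraction with a one-sided binomial
#' upper tail \eqn{P(X \ge k \mid n, p_0)}, where \eqn{p_0} is the
#' background fraction floored at \code{1/(2 n_bg)} (a hypergeometric test
#' on the pooled window set is available for small fixed backgrounds).
#'
#' @param target_seqs character vector of target window sequences.
#' @param background_seqs character vector of background window sequences.
#' @param pwms list of \code{pwm} objects.
#' @param threshold_frac hit threshold passed to \code{\link{scan_pwm}}.
#' @param alpha significance threshold on the raw P (study gate: 0.01).
#' @param method \code{"binomial"} (default) or \code{"hypergeometric"}.
#' @return data.frame sorted by P: \code{motif, tf, k, n, k_bg, n_bg,
#'   fraction_target, fraction_bg, p, q, significant} (q = Benjamini-
#'   Hochberg adjusted, reported alongside but not used for the gate).
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             threshold_frac = 0.8, alpha = 0.01,
                             method = c("binomial", "hypergeometric")) {
  method <- match.arg(method)
  if (!length(pwms)) stop2("empty PWM library")
  if (!length(target_seqs) || !length(background_seqs)) {
    stop2("need >= 1 target and >= 1 background window")
  }
  n <- length(target_seqs); n_bg <- length(background_seqs)
  rows <- lapply(pwms, function(m) {
    k <- length(unique(scan_pwm(target_seqs, m, threshold_frac)$seq_index))
    k_bg <- length(unique(scan_pwm(background_seqs, m, threshold_frac)$seq_index))
    p0 <- max(k_bg / n_bg, 1 / (2 * n_bg))
    p <- if (method == "binomial") {
      stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
    } else {
      hypergeom_upper_tail(k, k + k_bg, n, n + n_bg)
    }
    data.frame(motif = m$name, tf = m$tf_name, k = k, n = n,
               k_bg = k_bg, n_bg = n_bg, fraction_target = k / n,
               fraction_bg = k_bg / n_bg, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify differentially expressed transcription factors (DETFs)
#'
#' An up-DETF has its motif enriched (P below the motif gate) in GAIN
#' regions and its own gene significantly upregulated; a down-DETF mirrors
#' this in LOSS regions.  TF names that cannot be mapped to a gene id are
#' excluded and counted.
#'
#' @param enrichment_gain,enrichment_loss outputs of
#'   \code{\link{motif_enrichment}} for GAIN and LOSS summit windows.
#' @param expression expression table.
#' @param tf_map optional data.frame \code{tf, gene_id}; by default TF
#'   names are used as gene ids directly.
#' @param alpha motif-enrichment significance gate.
#' @return data.frame \code{tf, gene_id, direction, enrichment_p, log2fc,
#'   expression_level} (level = log2(FPKM + 1) of the case-group mean);
#'   unmappable-TF count in attribute \code{"n_unmapped"}.
#' @export
identify_detfs <- function(enrichment_gain, enrichment_loss, expression,
                           tf_map = NULL, alpha = 0.01) {
  map_tf <- function(tf) {
    if (is.null(tf_map)) return(tf)
    tf_map$gene_id[match(tf, tf_map$tf)]
  }
  one_side <- function(enr, direction) {
    enr <- enr[enr$p < alpha, , drop = FALSE]
    if (!nrow(enr)) return(NULL)
    gid <- map_tf(enr$tf)
    i <- match(gid, expression$gene_id)
    keep <- !is.na(gid) & !is.na(i)
    n_unmapped <<- n_unmapped + sum(!keep)
    enr <- enr[keep, , drop = FALSE]; i <- i[keep]; gid <- gid[keep]
    fc <- expression$log2fc[i]
    sig <- expression$significant[i]
    want <- if (direction == "up") sig & fc > 0 else sig & fc < 0
    if (!any(want)) return(NULL)
    data.frame(tf = enr$tf[want], gene_id = gid[want], direction = direction,
               enrichment_p = enr$p[want], log2fc = fc[want],
               expression_level = log2(expression$mean_case[i][want] + 1),
               stringsAsFactors = FALSE)
  }
  n_unmapped <- 0L
  out <- rbind(one_side(enrichment_gain, "up"),
               one_side(enrichment_loss, "down"))
  if (is.null(out)) {
    out <- data.frame(tf = character(), gene_id = character(),
                      direction = character(), enrichment_p = numeric(),
                      log2fc = numeric(), expression_level = numeric())
  }
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Motif occurrence profile around summits
#'
#' Re-extracts \code{[-halfwidth, +halfwidth)} windows around the summits,
#' scans them, and bins hit midpoints relative to the summit.  Density is
#' hits per bp per window, so
#' \eqn{\sum_{bins} density \times width \times n_{windows}} equals the
#' total hit count exactly.
#'
#' @param motif a \code{pwm}.
#' @param regions region/DER table with summits.
#' @param assets \code{genome_assets}.
#' @param halfwidth profile half-window in bp (study convention: -500 to
#'   +500).
#' @param bin bin width in bp.
#' @param threshold_frac hit threshold for \code{\link{scan_pwm}}.
#' @return object of class \code{occurrence_profile}: \code{breaks} (bin
#'   left edges relative to summit), \code{density}, \code{n_windows},
#'   \code{n_hits}.
#' @export
occurrence_profile <- function(motif, regions, assets, halfwidth = 500L,
                               bin = 10L, threshold_frac = 0.8) {
  win <- summit_windows(regions, assets, halfwidth)
  hits <- scan_pwm(win$seq, motif, threshold_frac)
  breaks <- seq(-halfwidth, halfwidth, by = bin)
  counts <- numeric(length(breaks) - 1L)
  if (nrow(hits)) {
    # genomic hit midpoint relative to the window's summit
    mid <- win$start[hits$seq_index] + hits$offset +
      floor(motif$length / 2) - win$summit[hits$seq_index]
    mid <- mid[mid >= -halfwidth & mid < halfwidth]
    counts <- tabulate(findInterval(mid, breaks), length(breaks) - 1L)
  }
  structure(list(breaks = head(breaks, -1L),
                 density = counts / (nrow(win) * bin),
                 bin = bin, n_windows = nrow(win), n_hits = sum(counts),
                 motif = motif$name),
            class = "occurrence_profile")
}

#' @export
print.occurrence_profile <- function(x, ...) {
  peak <- x$breaks[which.max(x$density)]
  cat("occurrence_profile for", x$motif, ":", x$n_hits, "hits over",
      x$n_windows, "windows; peak bin at", peak, "bp\n")
  invisible(x)
}

#' @export
plot.occurrence_profile <- function(x, ...) {
  graphics::plot(x$breaks + x$bin / 2, x$density, type = "l",
                 xlab = "distance from summit (bp)",
                 ylab = "hits / bp / window", ...)
  invisible(x)
}

#' Promoter-proximal target DEGs of a TF
#'
#' A DEG is a target of the TF when a PWM hit midpoint falls within
#' \code{[TSS - promoter_window, TSS + promoter_window)} (strand-agnostic
#' gate on genomic coordinates).  Targets are sorted by decreasing
#' |log2fc|.
#'
#' @param motif a \code{pwm}.
#' @param genes gene models.
#' @param expression expression table (targets must be DEGs).
#' @param assets \code{genome_assets}.
#' @param promoter_window promoter gate in bp around the TSS.
#' @param threshold_frac hit threshold for \code{\link{scan_pwm}}.
#' @return data.frame \code{gene_id, log2fc, n_sites, closest_site}
#'   (closest hit-midpoint distance to the TSS, bp).
#' @export
tf_targets <- function(motif, genes, expression, assets,
                       promoter_window = 2000L, threshold_frac = 0.8) {
  degs <- expression$gene_id[expression$significant]
  g <- genes[genes$gene_id %in% degs, , drop = FALSE]
  empty <- data.frame(gene_id = character(), log2fc = numeric(),
                      n_sites = integer(), closest_site = integer())
  if (!nrow(g)) return(empty)
  L <- motif$length
  # scan a slightly padded window so border sites score, then gate midpoints
  pad <- promoter_window + L
  win_start <- pmax(g$tss - pad, 0L)
  win_end <- pmin(g$tss + pad, unname(assets$chrom_sizes[g$chrom]))
  seqs <- vapply(seq_len(nrow(g)), function(i) {
    fetch_sequence(assets, g$chrom[i], win_start[i], win_end[i], "+")
  }, "")
  hits <- scan_pwm(seqs, motif, threshold_frac)
  if (!nrow(hits)) return(empty)
  mid <- win_start[hits$seq_index] + hits$offset + floor(L / 2)
  rel <- mid - g$tss[hits$seq_index]
  inside <- rel >= -promoter_window & rel < promoter_window
  hits <- hits[inside, , drop = FALSE]; rel <- rel[inside]
  if (!nrow(hits)) return(empty)
  by_gene <- split(abs(rel), hits$seq_index)
  gi <- as.integer(names(by_gene))
  out <- data.frame(gene_id = g$gene_id[gi],
                    log2fc = expression$log2fc[match(g$gene_id[gi],
                                                     expression$gene_id)],
                    n_sites = lengths(by_gene),
                    closest_site = vapply(by_gene, min, 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
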