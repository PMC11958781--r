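#' Assign each DER to its nearest gene within a distance gate
#'
#' Distance is |region midpoint - TSS|, strand-agnostic; DERs farther than
#' \code{max_dist} from every TSS are dropped (the drop count is attached
#' as the \code{"n_dropped"} attribute).  Ties go to the lexicographically
#' smallest \code{gene_id}.
#'
#' @param ders DER table from \code{\link{call_ders}}.
#' @param genes gene models.
#' @param expression optional expression table; when given, each
#'   assignment carries the gene's log2fc and DEG flag.
#' @param max_dist maximum midpoint-to-TSS distance in bp.
#' @return data.frame \code{region_id, class, der_log2fc, gene_id,
#'   distance} (+ \code{gene_log2fc, deg} with expression).
#' @export
assign_nearest_gene <- function(ders, genes, expression = NULL,
                                max_dist = 100000L) {
  if (nrow(ders) == 0L || nrow(genes) == 0L) {
    out <- data.frame(region_id = character(), class = character(),
                      der_log2fc = numeric(), gene_id = character(),
                      distance = numeric())
    attr(out, "n_dropped") <- nrow(ders)
    return(out)
  }
  mid <- interval_midpoint(ders)
  gene_id <- character(nrow(ders)); dist <- rep(Inf, nrow(ders))
  for (ch in unique(ders$chrom)) {
    ri <- which(ders$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    m <- mid[ri]
    pos <- findInterval(m, g$tss)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, nrow(g))
    d_lo <- abs(m - g$tss[lo]); d_hi <- abs(m - g$tss[hi])
    pick_hi <- d_hi < d_lo | (d_hi == d_lo & g$gene_id[hi] < g$gene_id[lo])
    ng <- ifelse(pick_hi, hi, lo)
    gene_id[ri] <- g$gene_id[ng]
    dist[ri] <- pmin(d_lo, d_hi)
  }
  keep <- dist <= max_dist
  out <- data.frame(region_id = ders$region_id[keep],
                    class = if ("class" %in% names(ders)) ders$class[keep]
                            else NA_character_,
                    der_log2fc = if ("log2fc" %in% names(ders))
                      ders$log2fc[keep] else NA_real_,
                    gene_id = gene_id[keep], distance = dist[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(expression)) {
    i <- match(out$gene_id, expression$gene_id)
    out$gene_log2fc <- expression$log2fc[i]
    out$deg <- expression$significant[i]
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Intersect DER-linked genes with DEGs
#'
#' A gene lands in a class when at least one assigned DER of that class
#' links to it and its DEG flag is set.  Genes absent from the expression
#' table are excluded (counted, not fatal).
#'
#' @param assignments output of \code{\link{assign_nearest_gene}}.
#' @param expression expression table.
#' @return list with \code{GAIN} and \code{LOSS} unique DEG gene vectors,
#'   per-class counts, and \code{n_missing_expression}.
#' @export
intersect_with_degs <- function(assignments, expression) {
  i <- match(assignments$gene_id, expression$gene_id)
  missing <- is.na(i)
  a <- assignments[!missing, , drop = FALSE]
  deg <- expression$significant[i[!missing]]
  pick <- function(cls) {
    sort(unique(a$gene_id[a$class == cls & deg]))
  }
  gain <- pick("GAIN"); loss <- pick("LOSS")
  list(GAIN = gain, LOSS = loss,
       counts = c(GAIN = length(gain), LOSS = length(loss)),
       n_missing_expression = sum(missing))
}

#' Pearson correlation between DER and gene fold changes
#'
#' By default each gene contributes one point: among its assigned DERs the
#' one with the largest |log2fc| represents it (one dot per gene, as in a
#' DER-DEG scatter).  \code{per_gene = FALSE} uses every assignment pair.
#'
#' @param assignments output of \code{\link{assign_nearest_gene}} with
#'   \code{gene_log2fc} present.
#' @param deg_only restrict to genes flagged as DEGs.
#' @param per_gene collapse to one representative DER per gene.
#' @return list \code{r, p, n} (class \code{correlation_result}); p is the
#'   two-sided Student-t P value of the product-moment coefficient.
#' @export
pearson_fc_correlation <- function(assignments, deg_only = FALSE,
                                   per_gene = TRUE) {
  a <- assignments[!is.na(assignments$gene_log2fc), , drop = FALSE]
  if (deg_only) a <- a[a$deg %in% TRUE, , drop = FALSE]
  if (per_gene && nrow(a)) {
    o <- order(a$gene_id, -abs(a$der_log2fc))
    a <- a[o, , drop = FALSE]
    a <- a[!duplicated(a$gene_id), , drop = FALSE]
  }
  if (nrow(a) < 3L) stop2("need >= 3 pairs for a correlation")
  x <- a$der_log2fc; y <- a$gene_log2fc
  if (sd(x) == 0 || sd(y) == 0) stop2("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(a)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, two-sided P = %.3g)\n",
              x$r, x$n, x$p))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences \code{x - y}; zero differences are dropped, tied |d| get
#' average ranks.  The null distribution of the positive-rank sum W is
#' exact (dynamic-programming enumeration over sign patterns) for
#' \code{n_eff <= exact_limit}, otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit maximum \code{n_eff} for the exact null.
#' @return list \code{W, n_eff, p} (class \code{signed_rank_result}).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop2("no information: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- exact_signed_rank_p(r, W)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(W = W, n_eff = n, p = p), class = "signed_rank_result")
}

# exact two-sided P of the signed-rank statistic given the rank vector.
# Ranks are on a half-integer grid with ties, so work on doubled ranks.
exact_signed_rank_p <- function(r, W) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  # distribution of the doubled positive-rank sum over all 2^n sign vectors
  f <- numeric(total + 1L)   # f[s+1] = #assignments with doubled sum s
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] + f[1:(total - ri + 1L)]
    f <- g
  }
  f <- f / 2^length(r2)
  w2 <- as.integer(round(2 * W))
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  p_le <- sum(f[1:(w2 + 1L)])
  min(1, 2 * min(p_ge, p_le))
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g (n_eff = %d), two-sided P = %.4g\n",
              x$W, x$n_eff, x$p))
  invisible(x)
}

#' Concordance between two histone marks' DERs
#'
#' Compares two marks through their nearest-gene assignments: shared genes,
#' the fraction whose fold changes agree in sign, and (given >= 3 shared
#' genes) the Pearson correlation of the per-gene representative log2fc.
#'
#' @param assign1,assign2 assignment tables from
#'   \code{\link{assign_nearest_gene}} for the two marks.
#' @return list \code{shared_genes, n_shared, sign_agreement, r}
#'   (\code{r = NA} with fewer than 3 shared genes).
#' @export
cross_mark_concordance <- function(assign1, assign2) {
  rep1 <- representative_fc(assign1)
  rep2 <- representative_fc(assign2)
  shared <- intersect(names(rep1), names(rep2))
  x <- rep1[shared]; y <- rep2[shared]
  agree <- if (length(shared)) mean(sign(x) == sign(y)) else NA_real_
  r <- if (length(shared) >= 3L && sd(x) > 0 && sd(y) > 0) {
    unname(cor(x, y))
  } else NA_real_
  list(shared_genes = shared, n_shared = length(shared),
       sign_agreement = agree, r = r)
}

representative_fc <- function(assignments) {
  a <- assignments[order(assignments$gene_id,
                         -abs(assignments$der_log2fc)), , drop = FALSE]
  a <- a[!duplicated(a$gene_id), , drop = FALSE]
  setNames(a$der_log2fc, a$gene_id)
}
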