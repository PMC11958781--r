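# Shared fixtures and independent oracles, all built in code.

# minimal rpkm_matrix without going through files
make_rpkm_matrix <- function(rpkm, groups, regions = NULL) {
  rpkm <- as.matrix(rpkm)
  if (is.null(colnames(rpkm))) colnames(rpkm) <- names(groups)
  if (is.null(regions)) {
    regions <- data.frame(region_id = sprintf("r%03d", seq_len(nrow(rpkm))),
                          chrom = "chr1",
                          start = seq_len(nrow(rpkm)) * 1000L,
                          end = seq_len(nrow(rpkm)) * 1000L + 500L,
                          stringsAsFactors = FALSE)
  }
  rownames(rpkm) <- regions$region_id
  structure(list(rpkm = rpkm, counts = NULL,
                 library_sizes = setNames(rep(NA_real_, ncol(rpkm)),
                                          colnames(rpkm)),
                 groups = groups[colnames(rpkm)], regions = regions,
                 mode = "fragments"),
            class = "rpkm_matrix")
}

toy_assets <- function(seqs) {
  genome_assets(setNames(nchar(seqs), names(seqs)), seqs)
}

random_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  toy_assets(setNames(paste(sample(c("A", "C", "G", "T"), len, TRUE),
                            collapse = ""), name))
}

toy_genes <- function(tss, strand = "+", chrom = "chr1", len = 1000L,
                      ids = NULL) {
  strand <- rep(strand, length.out = length(tss))
  tx_start <- ifelse(strand == "+", tss, tss - len + 1L)
  tx_end <- tx_start + len
  data.frame(gene_id = ids %||% sprintf("g%02d", seq_along(tss)),
             chrom = chrom, strand = strand,
             tx_start = tx_start, tx_end = tx_end,
             tss = ifelse(strand == "+", tx_start, tx_end - 1L),
             tes = ifelse(strand == "+", tx_end - 1L, tx_start),
             exon_starts = as.character(tx_start),
             exon_ends = as.character(tx_end),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ----------------------------------------------------

# brute-force fold-rule DER classification of one region
oracle_der_class <- function(mean_ctrl, mean_case, fold = 2, eps = 0.5) {
  up <- (mean_case + eps) / (mean_ctrl + eps)
  if (up > fold) return("GAIN")
  if (1 / up > fold) return("LOSS")
  NA_character_
}

# naive per-position, per-strand PWM rescoring (no vectorization tricks)
naive_scan <- function(seq, motif, threshold_frac = 0.8) {
  bases <- c("A", "C", "G", "T")
  revmap <- c(A = "T", C = "G", G = "C", T = "A")
  L <- motif$length
  chars <- strsplit(toupper(seq), "")[[1]]
  score_at <- function(site) {
    s <- 0
    for (i in seq_len(L)) {
      j <- match(site[i], bases)
      s <- s + if (is.na(j)) 0 else motif$score[i, j]
    }
    s
  }
  thr <- threshold_frac * motif$max_score
  out <- NULL
  if (length(chars) >= L) {
    for (t in seq_len(length(chars) - L + 1L)) {
      site <- chars[t:(t + L - 1L)]
      sf <- score_at(site)
      rc <- rev(unname(revmap[site]))
      rc[is.na(rc)] <- "N"
      sr <- score_at(rc)
      if (sf >= thr) out <- rbind(out, data.frame(offset = t - 1L,
                                                  strand = "+", score = sf))
      if (sr >= thr) out <- rbind(out, data.frame(offset = t - 1L,
                                                  strand = "-", score = sr))
    }
  }
  if (is.null(out)) data.frame(offset = integer(), strand = character(),
                               score = numeric()) else out
}

# exact signed-rank two-sided p by full 2^n enumeration of sign patterns
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
}

# hypergeometric upper tail by direct (non-log) summation
direct_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
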