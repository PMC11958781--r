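#' Read gene models from BED-like text
#'
#' Expected columns (tab-separated, no header): chrom, tx_start, tx_end,
#' gene_id, score, strand, exon_sizes, exon_starts.  Exon sizes/starts are
#' comma-separated lists; exon starts are relative to \code{tx_start}
#' (BED12 block convention).  A missing exon specification (fewer than 8
#' columns) yields a single exon spanning the transcript.
#'
#' The TSS is the first transcribed base: \code{tx_start} on the + strand
#' and \code{tx_end - 1} on the - strand (kept a valid coordinate); the TES
#' is the opposite end.
#'
#' @param path input file.
#' @param assets optional \code{genome_assets} for chromosome validation.
#' @return data.frame with columns \code{gene_id, chrom, strand, tx_start,
#'   tx_end, tss, tes, exon_starts, exon_ends} (the last two comma-separated
#'   absolute coordinates).
#' @export
read_gene_models <- function(path, assets = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE, colClasses = "character")
  if (nrow(dt) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tx_start = integer(),
                      tx_end = integer(), tss = integer(), tes = integer(),
                      exon_starts = character(), exon_ends = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(dt) < 6L) stop2(path, ": gene models need >= 6 columns")
  g <- data.frame(gene_id = dt[[4]], chrom = dt[[1]], strand = dt[[6]],
                  tx_start = as.integer(dt[[2]]), tx_end = as.integer(dt[[3]]),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$gene_id)) {
    stop2("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1])
  }
  if (!all(g$strand %in% c("+", "-"))) stop2("gene strand must be + or -")
  if (any(g$tx_start >= g$tx_end)) stop2("tx_start >= tx_end")
  check_chroms(g$chrom, assets)
  if (ncol(dt) >= 8L && any(nzchar(dt[[7]]))) {
    sizes <- strsplit(dt[[7]], ",", fixed = TRUE)
    rel <- strsplit(dt[[8]], ",", fixed = TRUE)
    es <- ee <- character(nrow(g))
    for (i in seq_len(nrow(g))) {
      s0 <- g$tx_start[i] + as.integer(rel[[i]])
      e0 <- s0 + as.integer(sizes[[i]])
      if (is.unsorted(s0, strictly = TRUE) || any(e0[-length(e0)] > s0[-1])) {
        stop2("gene ", g$gene_id[i], ": exons must be ordered, non-overlapping")
      }
      if (any(s0 < g$tx_start[i]) || any(e0 > g$tx_end[i])) {
        stop2("gene ", g$gene_id[i], ": exon outside transcript")
      }
      es[i] <- paste(s0, collapse = ",")
      ee[i] <- paste(e0, collapse = ",")
    }
    g$exon_starts <- es; g$exon_ends <- ee
  } else {
    g$exon_starts <- as.character(g$tx_start)
    g$exon_ends <- as.character(g$tx_end)
  }
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L)
  g$tes <- ifelse(g$strand == "+", g$tx_end - 1L, g$tx_start)
  g[, c("gene_id", "chrom", "strand", "tx_start", "tx_end", "tss", "tes",
        "exon_starts", "exon_ends")]
}

#' Write gene models in the BED-like layout read_gene_models() expects
#' @param genes gene-model data.frame.
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  rel <- mapply(function(s, t0) {
    paste(as.integer(strsplit(s, ",")[[1]]) - t0, collapse = ",")
  }, genes$exon_starts, genes$tx_start)
  sizes <- mapply(function(s, e) {
    paste(as.integer(strsplit(e, ",")[[1]]) -
          as.integer(strsplit(s, ",")[[1]]), collapse = ",")
  }, genes$exon_starts, genes$exon_ends)
  out <- data.frame(genes$chrom, genes$tx_start, genes$tx_end, genes$gene_id,
                    0L, genes$strand, sizes, rel)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# exon table for one gene row: data.frame(start, end), absolute coords
gene_exons <- function(gene_row) {
  data.frame(start = as.integer(strsplit(gene_row$exon_starts, ",")[[1]]),
             end = as.integer(strsplit(gene_row$exon_ends, ",")[[1]]))
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors; per-set descriptions are kept in
#'   the \code{"description"} attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) stop2(path, " line ", short[1], ": GMT needs >= 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop2("duplicate set name in ", path)
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)),
                                                  names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' Tab-separated with header \code{gene_id mean_ctrl mean_case log2fc
#' significant}; group means are FPKM-like (non-negative), \code{significant}
#' flags differentially expressed genes (DEGs).
#'
#' @param path TSV file.
#' @return data.frame with those five columns (\code{significant} logical).
#' @export
read_expression_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("gene_id", "mean_ctrl", "mean_case", "log2fc", "significant")
  if (!all(need %in% names(dt))) {
    stop2(path, ": expression table needs columns ",
          paste(need, collapse = ", "))
  }
  dt <- dt[, need]
  if (anyDuplicated(dt$gene_id)) {
    stop2("duplicate gene_id in expression table: ",
          dt$gene_id[duplicated(dt$gene_id)][1])
  }
  if (any(dt$mean_ctrl < 0) || any(dt$mean_case < 0)) {
    stop2("expression means must be non-negative")
  }
  dt$significant <- as.logical(dt$significant)
  dt
}

#' Write an expression table
#' @param expr expression data.frame.
#' @param path output file.
#' @export
write_expression_table <- function(expr, path) {
  data.table::fwrite(expr, path, sep = "\t", quote = FALSE)
  invisible(path)
}
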