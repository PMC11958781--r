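#' Read genomic intervals from tab-separated text
#'
#' All coordinates in the package are 0-based half-open (BED-native).
#' Supported formats:
#' \describe{
#'   \item{bed3}{chrom, start, end}
#'   \item{bed6}{bed3 + name, score, strand}
#'   \item{narrowpeak}{bed6 + signalValue, pValue, qValue, summit offset
#'     (column 10, relative to start; -1 means absent)}
#'   \item{fragments}{bed3; per-fragment intervals from paired-end
#'     sequencing}
#'   \item{bedgraph}{chrom, start, end, value (a piecewise-constant signal
#'     track)}
#' }
#'
#' @param path input file.
#' @param format one of \code{"bed3"}, \code{"bed6"}, \code{"narrowpeak"},
#'   \code{"fragments"}, \code{"bedgraph"}.
#' @param assets optional \code{genome_assets}; when given, chromosomes are
#'   validated against it.
#' @return data.frame of intervals in file order.  bedgraph yields columns
#'   \code{chrom,start,end,value}; narrowpeak adds a \code{summit} column
#'   (offset from start, \code{NA} when absent).
#' @export
read_intervals <- function(path,
                           format = c("bed3", "bed6", "narrowpeak",
                                      "fragments", "bedgraph"),
                           assets = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("no such file: ", path)
  need <- switch(format, bed3 = 3L, bed6 = 6L, narrowpeak = 10L,
                 fragments = 3L, bedgraph = 4L)
  if (file.size(path) == 0L) return(empty_intervals(format))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE),
    error = function(e) stop2("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(dt) == 0L) {
    out <- empty_intervals(format)
    return(out)
  }
  if (ncol(dt) < need) {
    stop2(path, ": expected >= ", need, " columns for ", format,
          ", found ", ncol(dt))
  }
  chrom <- as.character(dt[[1]])
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0L)
  if (length(bad)) {
    stop2(path, " line ", bad[1], ": coordinates must be non-negative integers")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop2(path, " line ", bad[1], ": start >= end")
  }
  check_chroms(chrom, assets)
  if (!is.null(assets)) {
    over <- which(end > assets$chrom_sizes[chrom])
    if (length(over)) {
      stop2(path, " line ", over[1], ": interval exceeds chromosome length")
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (format == "bedgraph") {
    out$value <- as.numeric(dt[[4]])
    if (anyNA(out$value)) {
      stop2(path, " line ", which(is.na(out$value))[1],
            ": bedgraph value not numeric")
    }
    return(out)
  }
  if (format %in% c("bed6", "narrowpeak")) {
    out$name <- as.character(dt[[4]])
    out$score <- suppressWarnings(as.numeric(dt[[5]]))
    out$strand <- as.character(dt[[6]])
    if (!all(out$strand %in% c("+", "-", "."))) {
      stop2(path, " line ", which(!out$strand %in% c("+", "-", "."))[1],
            ": strand must be one of +, -, .")
    }
  }
  if (format == "narrowpeak") {
    summit <- suppressWarnings(as.integer(dt[[10]]))
    summit[!is.na(summit) & summit < 0L] <- NA_integer_
    bad <- which(!is.na(summit) & summit >= out$end - out$start)
    if (length(bad)) {
      stop2(path, " line ", bad[1], ": summit offset outside region")
    }
    out$summit <- summit
  }
  out
}

empty_intervals <- function(format) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  if (format == "bedgraph") out$value <- numeric()
  if (format %in% c("bed6", "narrowpeak")) {
    out$name <- character(); out$score <- numeric(); out$strand <- character()
  }
  if (format == "narrowpeak") out$summit <- integer()
  out
}

#' Write intervals to BED / bedGraph text
#'
#' Writes exactly the columns present (\code{chrom,start,end} always;
#' \code{value} for tracks; \code{name,score,strand} for BED6), so that
#' \code{read_intervals(write_intervals(x))} round-trips canonical files.
#'
#' @param x intervals data.frame from \code{\link{read_intervals}}.
#' @param path output file.
#' @export
write_intervals <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "value", "name", "score",
                      "strand", "summit"), names(x))
  data.table::fwrite(x[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE, scipen = 50L)
  invisible(path)
}

iranges_of <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

#' Merge intervals closer than a gap
#'
#' Book-ended intervals (end of one equals start of the next) merge at
#' \code{gap = 0}, matching the dominant merge semantics of genomic toolkits.
#'
#' @param x intervals data.frame.
#' @param gap maximum distance (bp) at which two intervals still merge.
#' @return sorted, non-overlapping intervals (\code{chrom,start,end}).
#' @export
merge_intervals <- function(x, gap = 0L) {
  if (gap < 0) stop2("gap must be non-negative")
  if (nrow(x) == 0L) return(empty_intervals("bed3"))
  parts <- split(x, x$chrom)
  res <- lapply(names(parts)[order(names(parts))], function(ch) {
    r <- IRanges::reduce(iranges_of(parts[[ch]]), min.gapwidth = gap + 1L)
    data.frame(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count fragments overlapping each region
#'
#' A fragment counts toward a region when the two share at least one base
#' (half-open semantics: a fragment starting exactly at \code{region$end}
#' does not overlap).  A fragment may count toward several regions.
#'
#' @param regions intervals data.frame.
#' @param fragments intervals data.frame (\code{chrom,start,end}).
#' @return integer vector of counts, one per row of \code{regions}.
#' @export
count_overlapping_fragments <- function(regions, fragments) {
  n <- nrow(regions)
  counts <- integer(n)
  if (n == 0L || nrow(fragments) == 0L) return(counts)
  fsplit <- split(seq_len(nrow(fragments)), fragments$chrom)
  rsplit <- split(seq_len(n), regions$chrom)
  for (ch in names(rsplit)) {
    fi <- fsplit[[ch]]
    if (is.null(fi)) next
    ri <- rsplit[[ch]]
    hits <- IRanges::countOverlaps(
      iranges_of(regions[ri, , drop = FALSE]),
      iranges_of(fragments[fi, , drop = FALSE]))
    counts[ri] <- hits
  }
  counts
}

# midpoint of each interval (integer floor of (start+end)/2, a valid
# 0-based coordinate inside the interval)
interval_midpoint <- function(x) {
  as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
}
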