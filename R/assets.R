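#' Genome assets: chromosome sizes plus optional sequence
#'
#' Bundles a chromosome-size table with (optionally) the nucleotide sequence
#' of each chromosome.  Every interval-bearing function in the package
#' validates its chromosomes against this object when one is supplied.
#'
#' @param chrom_sizes named integer vector, chromosome name to length in bp.
#' @param seq optional \code{Biostrings::DNAStringSet} (or named character
#'   vector) holding one entry per chromosome; lengths must agree with
#'   \code{chrom_sizes}.
#' @return An object of class \code{genome_assets} with elements
#'   \code{chrom_sizes} and \code{seq}.
#' @export
genome_assets <- function(chrom_sizes, seq = NULL) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    stop2("chrom_sizes must be a named vector")
  }
  chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  if (any(chrom_sizes <= 0L)) stop2("chromosome lengths must be positive")
  if (!is.null(seq)) {
    if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
    if (!all(names(seq) %in% names(chrom_sizes))) {
      stop2("sequence names not present in chrom_sizes")
    }
    got <- Biostrings::width(seq)
    want <- unname(chrom_sizes[names(seq)])
    if (!all(got == want)) {
      bad <- names(seq)[got != want]
      stop2("sequence length disagrees with chrom_sizes for: ",
            paste(bad, collapse = ", "))
    }
  }
  structure(list(chrom_sizes = chrom_sizes, seq = seq),
            class = "genome_assets")
}

#' @export
print.genome_assets <- function(x, ...) {
  cat("genome_assets:", length(x$chrom_sizes), "chromosome(s),",
      format(sum(as.numeric(x$chrom_sizes)), big.mark = ","), "bp",
      if (is.null(x$seq)) "(sizes only)" else "(with sequence)", "\n")
  invisible(x)
}

#' Read a FASTA file into genome assets
#'
#' @param path FASTA file.
#' @return \code{genome_assets} with both sequence and sizes populated.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  genome_assets(setNames(Biostrings::width(seq), names(seq)), seq)
}

#' Write genome assets to FASTA
#'
#' @param assets \code{genome_assets} with sequence present.
#' @param path output file.
#' @export
write_fasta <- function(assets, path) {
  if (is.null(assets$seq)) stop2("assets carry no sequence")
  Biostrings::writeXStringSet(assets$seq, path, width = 70L)
  invisible(path)
}

check_chroms <- function(chrom, assets) {
  if (is.null(assets)) return(invisible(TRUE))
  unknown <- setdiff(unique(chrom), names(assets$chrom_sizes))
  if (length(unknown)) {
    stop2("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Extract a nucleotide subsequence
#'
#' Coordinates are 0-based half-open; \code{strand = "-"} returns the
#' reverse complement.
#'
#' @param assets \code{genome_assets} with sequence.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand \code{"+"}, \code{"-"} or \code{"."}.
#' @return character scalar of length \code{end - start}.
#' @export
fetch_sequence <- function(assets, chrom, start, end, strand = "+") {
  if (is.null(assets$seq)) stop2("assets carry no sequence")
  check_chroms(chrom, assets)
  size <- assets$chrom_sizes[[chrom]]
  if (start < 0 || end > size || start >= end) {
    stop2("interval [", start, ",", end, ") out of bounds on ", chrom,
          " (length ", size, ")")
  }
  s <- Biostrings::subseq(assets$seq[[chrom]], start + 1L, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}
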