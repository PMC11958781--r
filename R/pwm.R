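BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Counts are pseudocounted (\code{alpha} added to every cell) and
#' column-normalized to probabilities.  Scores are log2 odds against the
#' background, so a scanned site scores
#' \eqn{s = \sum_i \log_2(p_i(x_i)/b(x_i))}.
#'
#' @param counts 4 x L numeric matrix, rows in A, C, G, T order.
#' @param name motif identifier.
#' @param tf_name cognate transcription-factor name (defaults to
#'   \code{name}).
#' @param background base background probabilities (A,C,G,T), summing to 1.
#' @param alpha pseudocount added to each count before normalization.
#' @return object of class \code{pwm}: probabilities (L x 4), the log2-odds
#'   score matrix, background, and the maximum attainable score.
#' @export
pwm <- function(counts, name, tf_name = name,
                background = rep(0.25, 4), alpha = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop2("counts must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop2("negative counts")
  if (abs(sum(background) - 1) > 1e-9) stop2("background must sum to 1")
  if (alpha < 0 || (alpha == 0 && any(counts == 0))) {
    stop2("pseudocount must keep all probabilities positive")
  }
  p <- t(sweep(counts + alpha, 2, colSums(counts + alpha), "/"))  # L x 4
  colnames(p) <- BASES
  # raw base frequencies (no pseudocount): the motif's emission
  # distribution, used when sampling sites; zero-count bases never emit
  freq <- t(sweep(counts, 2, colSums(counts), "/"))
  colnames(freq) <- BASES
  score <- sweep(log2(p), 2, log2(background), "-")
  structure(list(name = name, tf_name = tf_name, prob = p, freq = freq,
                 score = score, background = background, alpha = alpha,
                 length = nrow(p), max_score = sum(apply(score, 1, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$name, "(", x$tf_name, "): length", x$length,
      "max log2-odds", round(x$max_score, 2), "\n")
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' One count on the consensus base at each position (IUPAC codes other than
#' A/C/G/T are not supported).
#'
#' @inheritParams pwm
#' @param consensus consensus string over A/C/G/T.
#' @export
pwm_from_consensus <- function(consensus, name = consensus,
                               tf_name = name, alpha = 0.01) {
  ch <- strsplit(toupper(consensus), "")[[1]]
  if (!all(ch %in% BASES)) stop2("consensus must be over A/C/G/T")
  counts <- matrix(0, 4, length(ch), dimnames = list(BASES, NULL))
  counts[cbind(match(ch, BASES), seq_along(ch))] <- 1
  pwm(counts, name, tf_name, alpha = alpha)
}

#' Read a JASPAR-style PFM text file
#'
#' Records start with \code{>motif_name TF_NAME}, followed by four count
#' rows in A, C, G, T order.  Rows may be bare numbers or JASPAR bracket
#' style (\code{A [ 3 10 ... ]}).
#'
#' @param path PFM file.
#' @param ... passed to \code{\link{pwm}} (background, pseudocount).
#' @return named list of \code{pwm} objects.
#' @export
read_pfm <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop2(path, ": no PFM records")
  ends <- c(heads[-1] - 1L, length(lines))
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[k]]), "\\s+")[[1]]
    body <- lines[(heads[k] + 1L):ends[k]]
    if (length(body) != 4L) {
      stop2(path, ": motif ", hdr[1], " needs exactly 4 count rows")
    }
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop2(path, ": motif ", hdr[1], " rows differ in length")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- BASES
    out[[k]] <- pwm(counts, name = hdr[1],
                    tf_name = if (length(hdr) > 1) hdr[2] else hdr[1], ...)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write PWMs as JASPAR-style PFM text (probabilities scaled to counts of 100)
#' @param pwms list of \code{pwm} objects.
#' @param path output file.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pwms) {
    writeLines(paste0(">", m$name, " ", m$tf_name), con)
    counts <- round(t(m$freq) * 100, 3)
    for (i in 1:4) {
      writeLines(paste(c(BASES[i], format(counts[i, ], trim = TRUE)),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

# encode A,C,G,T,N(+anything else) -> 1..5
encode_dna <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], BASES)
  v[is.na(v)] <- 5L
  v
}

#' Scan sequences with a PWM on both strands
#'
#' Scores every start position on both strands and reports hits whose
#' log2-odds score reaches \code{threshold_frac} of the maximum attainable
#' score.  N (or any non-ACGT) bases contribute 0 (the background odds).
#' Overlapping hits on the same strand of the same sequence are collapsed to
#' the best-scoring one (ties to the leftmost).
#'
#' @param seqs character vector of sequences (e.g. summit windows).
#' @param motif a \code{pwm}.
#' @param threshold_frac hit threshold as a fraction of the maximum score.
#' @param collapse collapse overlapping same-strand hits (best score wins);
#'   set FALSE to get every above-threshold position.
#' @return data.frame \code{seq_index, offset, strand, score}; \code{offset}
#'   is the 0-based start of the matched site on the forward coordinates of
#'   its sequence (for either strand the site occupies
#'   \code{[offset, offset + L)}).
#' @export
scan_pwm <- function(seqs, motif, threshold_frac = 0.8, collapse = TRUE) {
  stopifnot(inherits(motif, "pwm"))
  L <- motif$length
  keep <- nchar(seqs) >= L
  empty <- data.frame(seq_index = integer(), offset = integer(),
                      strand = character(), score = numeric())
  if (!any(keep)) return(empty)
  # concatenate all sequences with an L-long spacer that can never score
  S <- cbind(motif$score, 0)              # column 5: N -> background odds
  S <- cbind(S, -1e9)                     # column 6: spacer
  rc <- motif$score[L:1, c(4, 3, 2, 1), drop = FALSE]  # revcomp PWM
  Src <- cbind(rc, 0, -1e9)
  idx <- which(keep)
  codes <- lapply(seqs[idx], encode_dna)
  lens <- lengths(codes)
  spacer <- rep(6L, L)
  cat_codes <- unlist(lapply(codes, function(v) c(v, spacer)))
  n <- length(cat_codes)
  npos <- n - L + 1L
  fwd <- numeric(npos); rev <- numeric(npos)
  for (i in seq_len(L)) {
    sl <- cat_codes[i:(npos + i - 1L)]
    fwd <- fwd + S[i, sl]
    rev <- rev + Src[i, sl]
  }
  thr <- threshold_frac * motif$max_score
  # map concatenated positions back to (sequence, offset)
  starts <- cumsum(c(0L, head(lens + L, -1L)))      # 0-based seq starts
  hit_rows <- function(scores, strand) {
    p <- which(scores >= thr)
    if (!length(p)) return(empty)
    si <- findInterval(p - 1L, starts)
    off <- (p - 1L) - starts[si]
    ok <- off + L <= lens[si]                        # drop spacer windows
    data.frame(seq_index = idx[si[ok]], offset = as.integer(off[ok]),
               strand = strand, score = scores[p[ok]])
  }
  hits <- rbind(hit_rows(fwd, "+"), hit_rows(rev, "-"))
  if (nrow(hits) == 0L) return(empty)
  if (!collapse) {
    hits <- hits[order(hits$seq_index, hits$offset, hits$strand), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    return(hits)
  }
  collapse_hits(hits, L)
}

# greedy best-score collapse of overlapping same-strand hits
collapse_hits <- function(hits, L) {
  o <- order(hits$seq_index, hits$strand, -hits$score, hits$offset)
  hits <- hits[o, , drop = FALSE]
  keep <- logical(nrow(hits))
  grp <- paste(hits$seq_index, hits$strand)
  for (g in unique(grp)) {
    i <- which(grp == g)
    taken_s <- integer(0)
    for (j in i) {
      if (!any(hits$offset[j] < taken_s + L & hits$offset[j] + L > taken_s)) {
        keep[j] <- TRUE
        taken_s <- c(taken_s, hits$offset[j])
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$seq_index, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
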