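# sequence -> base indices 1..4 (A,C,G,T), NA for N or anything else
encode_seq <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "XString")) {
    seq <- as.character(seq)
  }
  match(strsplit(toupper(seq), "")[[1]], DNA)
}

# integer window scores for every start position; windows touching an NA
# base (N) come back NA. ints: width x 4 integer matrix.
window_int_scores <- function(idx, ints) {
  w <- nrow(ints)
  L <- length(idx)
  if (L < w) return(integer(0))
  n <- L - w + 1
  sc <- numeric(n)
  for (i in seq_len(w)) {
    sc <- sc + ints[i, ][idx[i:(i + n - 1)]]
  }
  sc
}

# exact log-odds (bits) of each window, same layout as window_int_scores
window_bit_scores <- function(idx, lo) {
  w <- nrow(lo)
  n <- length(idx) - w + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (i in seq_len(w)) {
    sc <- sc + lo[i, ][idx[i:(i + n - 1)]]
  }
  sc
}

# reverse-complement a width x 4 (A,C,G,T) matrix: reverse rows, swap A<->T
# and C<->G columns
revcomp_matrix <- function(m) {
  m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
}

empty_hits <- function() {
  data.frame(sequence_id = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             pwm_name = character(0), score = numeric(0),
             p_value = numeric(0))
}

#' Scan a sequence for PWM matches at an exact p-value threshold
#'
#' Slides the motif over the sequence (both strands by default), scores
#' every window by summed log-odds, and reports windows whose exact
#' p-value under the background null — from [score_distribution] — is at
#' or below `p_threshold`. Windows containing N are skipped. Minus-strand
#' hits report plus-strand coordinates of the window. Overlapping hits are
#' all reported.
#'
#' @param seq Character or `DNAString` sequence over A/C/G/T/N.
#' @param x A [pwm].
#' @param p_threshold Per-match p-value threshold (default 0.001).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param sequence_id Identifier recorded in the hit table.
#' @param dist Optional precomputed [score_distribution] for `x` (reused
#'   across sequences for speed).
#' @param granularity Discretisation step when `dist` is NULL.
#' @return data.frame of motif hits with columns `sequence_id`, `start`
#'   (0-based), `end` (exclusive), `strand`, `pwm_name`, `score` (bits),
#'   `p_value`, sorted by (start, strand). Sequences shorter than the
#'   motif yield zero rows.
#' @export
scan_pwm <- function(seq, x, p_threshold = 0.001, both_strands = TRUE,
                     sequence_id = "seq", dist = NULL,
                     granularity = 1 / 1000) {
  stopifnot(inherits(x, "pwm"))
  if (is.null(dist)) dist <- score_distribution(x, granularity)
  idx <- encode_seq(seq)
  w <- nrow(dist$ints)
  if (length(idx) < w) return(empty_hits())
  lo <- log_odds(x)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (st in strands) {
    ints <- if (st == "+") dist$ints else revcomp_matrix(dist$ints)
    lom <- if (st == "+") lo else revcomp_matrix(lo)
    isc <- window_int_scores(idx, ints)
    ok <- which(!is.na(isc))
    if (!length(ok)) next
    pv <- score_pvalue(dist, isc[ok])
    hit <- pv <= p_threshold
    if (!any(hit)) next
    bsc <- window_bit_scores(idx, lom)
    pos <- ok[hit]
    out[[st]] <- data.frame(sequence_id = sequence_id,
                            start = pos - 1L, end = pos - 1L + w,
                            strand = st, pwm_name = x$name,
                            score = bsc[pos], p_value = pv[hit])
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Scan with several PWMs (OR semantics)
#'
#' Union of the per-PWM hit sets; an element "harbours a motif" iff this
#' table is non-empty for its sequence.
#'
#' @param seq Sequence as in [scan_pwm].
#' @param pwms List of [pwm] objects (at least one).
#' @param dists Optional list of precomputed distributions, parallel to
#'   `pwms`.
#' @inheritParams scan_pwm
#' @return Hit data.frame sorted by (start, strand, pwm_name).
#' @export
scan_multi <- function(seq, pwms, p_threshold = 0.001, both_strands = TRUE,
                       sequence_id = "seq", dists = NULL,
                       granularity = 1 / 1000) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!length(pwms)) stop("scan_multi needs at least one PWM")
  res <- do.call(rbind, lapply(seq_along(pwms), function(i) {
    scan_pwm(seq, pwms[[i]], p_threshold = p_threshold,
             both_strands = both_strands, sequence_id = sequence_id,
             dist = if (is.null(dists)) NULL else dists[[i]],
             granularity = granularity)
  }))
  res <- res[order(res$start, res$strand, res$pwm_name), ]
  rownames(res) <- NULL
  res
}

#' Excise a motif hit from a sequence
#'
#' Reporter-construct design: removes the bases of the selected hit,
#' shortening the sequence by the motif width. The default selection picks
#' the hit with the lowest p-value, ties broken by leftmost start.
#'
#' @param seq Character sequence.
#' @param hits Hit data.frame from [scan_pwm]/[scan_multi]; must be
#'   non-empty and within the sequence bounds.
#' @param selection Only `"lowest_p"` is defined.
#' @return List with `sequence` (edited) and `removed` (the excised hit
#'   row).
#' @export
delete_motif <- function(seq, hits, selection = "lowest_p") {
  if (inherits(seq, "XString")) seq <- as.character(seq)
  if (is.null(hits) || !nrow(hits)) stop("no motif to delete")
  selection <- match.arg(selection, "lowest_p")
  if (any(hits$start < 0) || any(hits$end > nchar(seq))) {
    stop("motif hit outside the sequence bounds")
  }
  o <- order(hits$p_value, hits$start)
  pick <- hits[o[1], , drop = FALSE]
  edited <- paste0(substr(seq, 1, pick$start),
                   substr(seq, pick$end + 1, nchar(seq)))
  list(sequence = edited, removed = pick)
}

#' Scan genomic intervals against a genome
#'
#' Extracts each interval's sequence from a `DNAStringSet` keyed by
#' chromosome name and runs [scan_multi]; hit coordinates stay relative to
#' the element sequence, with the element id in `sequence_id`.
#'
#' @param cres `GRanges` of elements.
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @inheritParams scan_multi
#' @return Hit data.frame over all elements.
#' @export
scan_intervals <- function(cres, genome, pwms, p_threshold = 0.001,
                           both_strands = TRUE, granularity = 1 / 1000) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  dists <- lapply(pwms, score_distribution, granularity = granularity)
  ids <- cre_id(cres)
  chroms <- as.character(GenomicRanges::seqnames(cres))
  out <- vector("list", length(cres))
  for (i in seq_along(cres)) {
    if (!(chroms[i] %in% names(genome))) {
      stop("element ", ids[i], ": chromosome absent from the genome FASTA")
    }
    chrom_seq <- genome[[chroms[i]]]
    if (GenomicRanges::end(cres)[i] > length(chrom_seq)) {
      stop("element ", ids[i], ": interval extends past the FASTA sequence")
    }
    s <- as.character(Biostrings::subseq(chrom_seq,
                                         GenomicRanges::start(cres)[i],
                                         GenomicRanges::end(cres)[i]))
    out[[i]] <- scan_multi(s, pwms, p_threshold = p_threshold,
                           both_strands = both_strands,
                           sequence_id = ids[i], dists = dists)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_hits())
  rownames(res) <- NULL
  res
}
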