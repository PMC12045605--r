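#' Construct a set of genomic intervals
#'
#' Builds a \link[GenomicRanges]{GRanges} from BED-convention coordinates
#' (0-based, half-open). All file formats read and written by this package
#' use the BED convention; the in-memory container is a standard `GRanges`
#' (1-based, closed), converted once here at the boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start0 Integer vector, 0-based inclusive start positions.
#' @param end0 Integer vector, 0-based exclusive end positions.
#' @param strand Strand codes (`"+"`, `"-"` or `"."`), recycled.
#' @param name Optional interval identifiers.
#' @param score Optional numeric scores.
#' @param sizes Optional named vector of chromosome lengths; when supplied,
#'   every interval is validated against it (known chromosome, end within
#'   bounds) and the lengths are attached as `seqlengths`.
#' @return A `GRanges` object sorted by (chrom, start, end).
#' @export
genomic_intervals <- function(chrom, start0, end0, strand = ".",
                              name = NULL, score = NULL, sizes = NULL) {
  chrom <- as.character(chrom)
  start0 <- as.numeric(start0)
  end0 <- as.numeric(end0)
  bad <- which(!(start0 >= 0 & start0 < end0))
  if (length(bad)) {
    stop(sprintf("invalid interval (need 0 <= start < end): %s:[%s,%s)",
                 chrom[bad[1]], format(start0[bad[1]], scientific = FALSE),
                 format(end0[bad[1]], scientific = FALSE)))
  }
  strand <- gsub("\\.", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  # lexicographic seqlevels keep every downstream sort deterministic
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  if (!is.null(sizes)) gr <- attach_sizes(gr, sizes)
  sort_intervals(gr)
}

#' @rdname genomic_intervals
#' @param gr A `GRanges`.
#' @export
interval_start0 <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname genomic_intervals
#' @export
interval_end0 <- function(gr) GenomicRanges::end(gr)

#' Read a two-column chromosome-sizes table
#'
#' @param path Tab-delimited file with columns chromosome name and length.
#' @return Named integer vector of strictly positive lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (any(df$length <= 0)) {
    stop("chromosome lengths must be strictly positive in ", path)
  }
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome name in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Validate intervals against chromosome sizes and attach them
#'
#' Errors when an interval lies on an unknown chromosome or extends past
#' the chromosome end. Chromosome-name mismatches (e.g. `chr1` vs `1`) are
#' reported, never silently harmonised.
#'
#' @param gr A `GRanges`.
#' @param sizes Named vector of chromosome lengths.
#' @return `gr` with `seqlengths` set.
#' @export
attach_sizes <- function(gr, sizes) {
  used <- as.character(unique(GenomicRanges::seqnames(gr)))
  unknown <- setdiff(used, names(sizes))
  if (length(unknown)) {
    stop("unknown chromosome(s) not in the sizes table: ",
         paste(unknown, collapse = ", "))
  }
  over <- GenomicRanges::end(gr) >
    unname(sizes[as.character(GenomicRanges::seqnames(gr))])
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("interval %s:[%d,%d) extends past the chromosome end",
                 as.character(GenomicRanges::seqnames(gr))[i],
                 interval_start0(gr)[i], interval_end0(gr)[i]))
  }
  lv <- sort(union(GenomeInfoDb::seqlevels(gr), names(sizes)))
  GenomeInfoDb::seqlevels(gr) <- lv
  GenomeInfoDb::seqlengths(gr) <- unname(sizes[lv])
  gr
}

# deterministic (chrom lexicographic, start, end) ordering used for all outputs
sort_intervals <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Per-base intersection of two interval sets
#'
#' Returns the maximal regions covered by at least one interval of `a` and
#' at least one interval of `b` (strand-blind, >= 1 shared base), the
#' operation used to derive active enhancers from ATAC and H3K27Ac peaks.
#'
#' @param a,b `GRanges` interval sets.
#' @return Sorted `GRanges` of overlap regions. When the two sets share no
#'   chromosome names a warning is raised and the result is empty.
#' @export
interval_intersect <- function(a, b) {
  if (length(a) && length(b)) {
    sa <- as.character(unique(GenomicRanges::seqnames(a)))
    sb <- as.character(unique(GenomicRanges::seqnames(b)))
    if (!length(intersect(sa, sb))) {
      warning("interval sets share no chromosome names (",
              paste(utils::head(sa, 3), collapse = ","), " vs ",
              paste(utils::head(sb, 3), collapse = ","),
              "); returning an empty set")
      return(GenomicRanges::GRanges())
    }
  }
  lv <- sort(union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b)))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  res <- GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  sort_intervals(res)
}

#' Extend intervals symmetrically, clamped to chromosome bounds
#'
#' The BEDTools "slop" operation: each interval grows by `flank` bp on both
#' sides and is clamped to `[0, chromosome length)`.
#'
#' @param gr A `GRanges`.
#' @param flank Non-negative flank in bp.
#' @param sizes Named vector of chromosome lengths (required for clamping at
#'   the right edge; every chromosome in `gr` must be present).
#' @return Extended, sorted `GRanges`.
#' @export
interval_slop <- function(gr, flank, sizes) {
  if (flank < 0) stop("flank must be non-negative")
  used <- as.character(unique(GenomicRanges::seqnames(gr)))
  unknown <- setdiff(used, names(sizes))
  if (length(unknown)) {
    stop("slop: chromosome(s) missing from the sizes table: ",
         paste(unknown, collapse = ", "))
  }
  if (!length(gr)) return(gr)
  len <- unname(sizes[as.character(GenomicRanges::seqnames(gr))])
  GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr) - flank)
  GenomicRanges::end(gr) <- pmin(len, GenomicRanges::end(gr) + flank)
  sort_intervals(gr)
}

#' Pairwise interval overlap predicate
#'
#' TRUE iff the two intervals share at least one base on the same
#' chromosome; strand is ignored and half-open adjacency does not count.
#' Vectorised over pairs (elements are recycled as in `GRanges` arithmetic
#' is not attempted; lengths must match or one must be 1).
#'
#' @param a,b `GRanges` of equal length (or either of length 1).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1) a <- rep(a, n)
  if (length(b) == 1) b <- rep(b, n)
  if (length(a) != length(b)) stop("interval_overlaps: length mismatch")
  as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b)) &
    GenomicRanges::start(a) <= GenomicRanges::end(b) &
    GenomicRanges::start(b) <= GenomicRanges::end(a)
}

#' Read and write BED files
#'
#' BED3/BED6, tab-delimited, 0-based half-open. `track`, `browser` and `#`
#' comment lines are skipped. Malformed lines (fewer than 3 columns,
#' non-integer coordinates, empty intervals) raise an error naming the line
#' number. Writing sorts intervals and emits BED6 when name/score/strand
#' information is present, BED3 otherwise; the round trip is lossless.
#'
#' @param path File path.
#' @param sizes Optional chromosome sizes for validation.
#' @return `read_bed`: a sorted `GRanges`.
#' @export
read_bed <- function(path, sizes = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("BED line %d: fewer than 3 columns", idx[which(ncol < 3)[1]]))
  }
  chrom <- vapply(fields, `[`, "", 1)
  s_raw <- vapply(fields, `[`, "", 2)
  e_raw <- vapply(fields, `[`, "", 3)
  s <- suppressWarnings(as.numeric(s_raw))
  e <- suppressWarnings(as.numeric(e_raw))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad)) {
    stop(sprintf("BED line %d: non-integer coordinates '%s'/'%s'",
                 idx[which(bad)[1]], s_raw[which(bad)[1]], e_raw[which(bad)[1]]))
  }
  bad <- s >= e
  if (any(bad)) {
    stop(sprintf("BED line %d: empty or inverted interval (start >= end)",
                 idx[which(bad)[1]]))
  }
  name <- if (any(ncol >= 4)) vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", "") else NULL
  score <- if (any(ncol >= 5)) {
    sc <- vapply(fields, function(f) if (length(f) >= 5) f[5] else "0", "")
    suppressWarnings(as.numeric(sc))
  } else NULL
  strand <- if (any(ncol >= 6)) vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", "") else "."
  genomic_intervals(chrom, s, e, strand = strand, name = name, score = score,
                    sizes = sizes)
}

#' @rdname read_bed
#' @param gr A `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  gr <- sort_intervals(gr)
  mc <- S4Vectors::mcols(gr)
  has6 <- ("name" %in% names(mc)) || ("score" %in% names(mc)) ||
    any(as.character(GenomicRanges::strand(gr)) != "*")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = interval_start0(gr),
                   end = interval_end0(gr))
  if (has6) {
    df$name <- if ("name" %in% names(mc)) mc$name else "."
    df$score <- if ("score" %in% names(mc)) mc$score else 0
    df$strand <- sub("\\*", ".", as.character(GenomicRanges::strand(gr)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
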