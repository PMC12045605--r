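#' Read a disease-locus table
#'
#' Tab-delimited with header: `locus_id`, `chrom`, `start`, `end` (BED
#' convention), `causative_gene` (empty when unresolved), `phenotype`.
#' Cytogenetic-band loci must arrive pre-resolved to coordinates.
#'
#' @param path File path.
#' @return data.frame of loci; `causative_gene` is `NA` when unresolved.
#' @export
read_disease_loci <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""),
                          quote = "", comment.char = "")
  need <- c("locus_id", "chrom", "start", "end", "causative_gene", "phenotype")
  if (!all(need %in% names(df))) {
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start < 0 | df$start >= df$end)) stop("invalid locus interval")
  df[, need]
}

#' Split loci by causative-gene status
#'
#' A locus is resolved iff a causative gene is recorded.
#'
#' @param loci data.frame from [read_disease_loci] (or with the same
#'   columns).
#' @return List with `resolved` and `unresolved` data.frames.
#' @export
partition_loci <- function(loci) {
  resolved <- !is.na(loci$causative_gene) & nzchar(loci$causative_gene)
  message(sum(resolved), " resolved / ", sum(!resolved), " unresolved loci")
  list(resolved = loci[resolved, , drop = FALSE],
       unresolved = loci[!resolved, , drop = FALSE])
}

#' Genes located within extended loci
#'
#' Each locus is extended by `flank` bp on both sides ([interval_slop])
#' and a gene is reported when its gene span shares at least one base with
#' any extended locus.
#'
#' @param gm A [gene_models] object.
#' @param loci data.frame of loci (typically the unresolved partition).
#' @param flank Extension in bp (default 100).
#' @param sizes Named chromosome lengths for clamping; defaults to an
#'   effectively unbounded right edge when omitted.
#' @return Sorted character vector of gene ids.
#' @export
genes_in_loci <- function(gm, loci, flank = 100, sizes = NULL) {
  if (!nrow(loci) || !length(gm)) return(character(0))
  lgr <- genomic_intervals(loci$chrom, loci$start, loci$end,
                           name = loci$locus_id)
  if (is.null(sizes)) {
    sizes <- stats::setNames(
      rep(.Machine$integer.max,
          length(unique(as.character(GenomicRanges::seqnames(lgr))))),
      unique(as.character(GenomicRanges::seqnames(lgr))))
  }
  lgr <- interval_slop(lgr, flank, sizes)
  spans <- gene_span_gr(gm)
  hit <- IRanges::overlapsAny(spans, lgr, ignore.strand = TRUE)
  sort(unique(S4Vectors::mcols(spans)$name[hit]))
}

#' Map gene identifiers through an ortholog table
#'
#' @param source_genes Character vector of source-species gene ids.
#' @param mapping data.frame with columns `source_id`, `target_id`; a
#'   source may map to several targets and some sources may be absent
#'   (expected — they are reported, not an error).
#' @return List with `mapped` (sorted unique target ids) and `unmapped`
#'   (source ids without a mapping row).
#' @export
map_orthologs <- function(source_genes, mapping) {
  stopifnot(all(c("source_id", "target_id") %in% names(mapping)))
  source_genes <- unique(source_genes)
  rows <- mapping[mapping$source_id %in% source_genes, , drop = FALSE]
  unmapped <- sort(setdiff(source_genes, rows$source_id))
  if (length(unmapped)) {
    message(length(unmapped), " source gene(s) without an ortholog: ",
            paste(utils::head(unmapped, 10), collapse = ", "))
  }
  list(mapped = sort(unique(rows$target_id)), unmapped = unmapped)
}

#' One-tailed enrichment test for targets in disease loci
#'
#' Fisher's exact one-tailed test of whether targets fall inside
#' (extended, unresolved) disease loci more often than expected:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` drawing `n` targets
#' from a universe of `N` genes of which `K` lie in loci.
#'
#' @param k Targets inside loci.
#' @param n Total targets.
#' @param K Universe genes inside loci.
#' @param N Universe size.
#' @param alpha Significance level (default 0.1).
#' @return List of class `enrichment_result`: `k`, `n`, `K`, `N`,
#'   `p_value`, `alpha`, `significant`.
#' @export
fisher_enrichment <- function(k, n, K, N, alpha = 0.1) {
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > n || k > K || K > N || n > N ||
      (n - k) > (N - K)) {
    stop("inconsistent enrichment counts (need k <= min(n, K), n <= N, K <= N)")
  }
  tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(k = k, n = n, K = K, N = N, p_value = p, alpha = alpha,
                 significant = p <= alpha),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d targets in loci vs %d/%d universe; one-tailed p = %.4g (%ssignificant at alpha = %g)\n",
              x$k, x$n, x$K, x$N, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Cross-reference putative targets against locus genes
#'
#' @param targets Character vector of target gene ids (non-empty).
#' @param in_loci Character vector of gene ids located in (extended)
#'   disease loci.
#' @return List with `overlap` (sorted ids in both sets), `k`, `n` and
#'   `percentage` (`round(100 * k / n)` to the nearest integer).
#' @export
crossref_targets <- function(targets, in_loci) {
  targets <- unique(targets)
  if (!length(targets)) stop("empty target set")
  ov <- sort(intersect(targets, unique(in_loci)))
  k <- length(ov)
  n <- length(targets)
  list(overlap = ov, k = k, n = n, percentage = round(100 * k / n))
}
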