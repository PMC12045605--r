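#' Derive active enhancers from ATAC and H3K27Ac peaks
#'
#' Active enhancers are the per-base intersection of open-chromatin (ATAC)
#' and H3K27Ac peaks with promoter- and exon-overlapping fragments removed;
#' intersection precedes classification, and each surviving fragment gets a
#' fresh stable id (`chrom:start-end`) — fragments are the countable
#' element unit throughout the pipeline.
#'
#' @param atac,h3k27ac `GRanges` peak sets on the same genome.
#' @param gm A [gene_models] object.
#' @param promoter_window Promoter half-width in bp (default 1000).
#' @return Sorted `GRanges` with a `name` column holding element ids; empty
#'   (with a warning) when either input is empty.
#' @export
active_enhancers <- function(atac, h3k27ac, gm, promoter_window = 1000) {
  if (!length(atac) || !length(h3k27ac)) {
    warning("empty peak set: no active enhancers")
    return(GenomicRanges::GRanges())
  }
  cres <- interval_intersect(atac, h3k27ac)
  cres <- filter_enhancers(cres, gm, promoter_window)
  if (length(cres)) S4Vectors::mcols(cres)$name <- cre_id(cres)
  cres
}

#' Expression-enriched genes
#'
#' Genes passing the enrichment filter `fold_change > fc_min` AND
#' `fpkm > fpkm_min`, both strictly.
#'
#' @param expr data.frame with one row per gene: `gene_id`, `fold_change`
#'   (linear scale, > 0), `fpkm` (>= 0).
#' @param fc_min Fold-change threshold (default 2).
#' @param fpkm_min Expression-level threshold (default 10).
#' @return Character vector of gene ids, sorted.
#' @export
enriched_genes <- function(expr, fc_min = 2, fpkm_min = 10) {
  stopifnot(all(c("gene_id", "fold_change", "fpkm") %in% names(expr)))
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicate gene_id in the expression table: ",
         expr$gene_id[duplicated(expr$gene_id)][1])
  }
  if (any(expr$fold_change <= 0, na.rm = TRUE)) {
    stop("fold_change must be positive")
  }
  sort(expr$gene_id[!is.na(expr$fold_change) & !is.na(expr$fpkm) &
                    expr$fold_change > fc_min & expr$fpkm > fpkm_min])
}

#' Call putative transcription-factor target genes
#'
#' The composed pipeline: scan every active element's sequence with the
#' supplied PWMs at the p-value threshold, keep elements with at least one
#' hit, softly assign them to all TSSs within the window, and call a gene
#' a putative target iff it is expression-enriched and receives at least
#' one motif-bearing element. Deterministic given its inputs.
#'
#' An element assigned to several enriched genes supports all of them but
#' is counted once in `summary$n_cres`.
#'
#' @param cres `GRanges` of active enhancers (see [active_enhancers]).
#' @param gm A [gene_models] object.
#' @param expr Expression table (see [enriched_genes]).
#' @param pwms List of [pwm] objects.
#' @param genome Named `DNAStringSet` or character vector of chromosome
#'   sequences.
#' @param window TSS assignment window in bp (default 35000).
#' @param p_threshold Motif p-value threshold (default 0.001).
#' @param fc_min,fpkm_min Enrichment thresholds (defaults 2 and 10).
#' @param granularity Score discretisation step in bits.
#' @return List of class `target_calls`:
#'   `targets` (data.frame `gene_id`, `n_cres`, `n_hits`, `cres`
#'   semicolon-separated), `cre_table` (per supporting element:
#'   `cre_id`, `gene_id`, `distance`, `n_hits`), `hits` (all motif hits in
#'   motif-bearing elements) and `summary` (`n_genes`, `n_cres`).
#' @export
call_targets <- function(cres, gm, expr, pwms, genome, window = 35000,
                         p_threshold = 0.001, fc_min = 2, fpkm_min = 10,
                         granularity = 1 / 1000) {
  empty <- structure(list(
    targets = data.frame(gene_id = character(0), n_cres = integer(0),
                         n_hits = integer(0), cres = character(0)),
    cre_table = data.frame(cre_id = character(0), gene_id = character(0),
                           distance = numeric(0), n_hits = integer(0)),
    hits = empty_hits(),
    summary = list(n_genes = 0L, n_cres = 0L)), class = "target_calls")
  if (!length(cres)) return(empty)
  hits <- scan_intervals(cres, genome, pwms, p_threshold = p_threshold,
                         granularity = granularity)
  if (!nrow(hits)) return(empty)
  n_hits_by_cre <- table(hits$sequence_id)
  bearing <- cres[cre_id(cres) %in% names(n_hits_by_cre)]
  assign <- assign_to_tss(bearing, gm, window = window)
  enr <- enriched_genes(expr, fc_min = fc_min, fpkm_min = fpkm_min)
  assign <- assign[assign$gene_id %in% enr, , drop = FALSE]
  if (!nrow(assign)) return(empty)
  assign$n_hits <- as.integer(n_hits_by_cre[assign$cre_id])
  targets <- do.call(rbind, lapply(split(assign, assign$gene_id), function(a) {
    data.frame(gene_id = a$gene_id[1], n_cres = nrow(a),
               n_hits = sum(a$n_hits),
               cres = paste(a$cre_id, collapse = ";"))
  }))
  targets <- targets[order(targets$gene_id), ]
  rownames(targets) <- NULL
  cre_table <- assign[order(assign$gene_id, assign$cre_id),
                      c("cre_id", "gene_id", "distance", "n_hits")]
  rownames(cre_table) <- NULL
  structure(list(targets = targets, cre_table = cre_table,
                 hits = hits[hits$sequence_id %in% assign$cre_id, ],
                 summary = list(n_genes = nrow(targets),
                                n_cres = length(unique(assign$cre_id)))),
            class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  cat("target_calls:", x$summary$n_genes, "putative target genes,",
      x$summary$n_cres, "supporting elements\n")
  invisible(x)
}
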