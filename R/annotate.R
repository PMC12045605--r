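#' Classify peaks relative to gene models
#'
#' Each peak receives a single category chosen by the fixed priority
#' promoter > exon > intron > intergenic: promoter if it overlaps the
#' `[tss - promoter_window, tss + promoter_window)` zone of any gene, else
#' exon if it overlaps any exon, else intron if it overlaps a gene span,
#' else intergenic. The nearest TSS (by absolute midpoint-to-TSS distance)
#' is reported with a signed distance: positive when the TSS lies
#' downstream of the peak midpoint in genome coordinates, independent of
#' gene strand.
#'
#' @param peaks `GRanges` of peaks.
#' @param gm A [gene_models] object.
#' @param promoter_window Half-width of the promoter zone in bp
#'   (default 1000).
#' @return data.frame with columns `chrom`, `start`, `end` (BED
#'   convention), `category`, `nearest_tss_gene`, `nearest_tss_distance`.
#' @export
classify_peaks <- function(peaks, gm, promoter_window = 1000) {
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                    start = interval_start0(peaks),
                    end = interval_end0(peaks))
  if (!length(peaks)) {
    out$category <- character(0)
    out$nearest_tss_gene <- character(0)
    out$nearest_tss_distance <- numeric(0)
    return(out)
  }
  if (!length(gm)) {
    warning("empty gene set: all peaks classified intergenic")
    out$category <- "intergenic"
    out$nearest_tss_gene <- NA_character_
    out$nearest_tss_distance <- NA_real_
    return(out)
  }
  in_prom <- IRanges::overlapsAny(peaks, gene_promoter_gr(gm, promoter_window),
                                        ignore.strand = TRUE)
  in_exon <- IRanges::overlapsAny(peaks, gene_exon_gr(gm),
                                        ignore.strand = TRUE)
  in_span <- IRanges::overlapsAny(peaks, gene_span_gr(gm),
                                        ignore.strand = TRUE)
  out$category <- ifelse(in_prom, "promoter",
                  ifelse(in_exon, "exon",
                  ifelse(in_span, "intron", "intergenic")))
  mid <- floor((out$start + out$end) / 2)
  g <- gm$genes
  nearest_gene <- character(nrow(out))
  nearest_dist <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    same <- g$chrom == out$chrom[i]
    if (!any(same)) {
      nearest_gene[i] <- NA_character_
      nearest_dist[i] <- NA_real_
      next
    }
    d <- g$tss[same] - mid[i]
    j <- which.min(abs(d))
    nearest_gene[i] <- g$gene_id[same][j]
    nearest_dist[i] <- d[j]
  }
  out$nearest_tss_gene <- nearest_gene
  out$nearest_tss_distance <- nearest_dist
  out
}

#' Keep only putative-enhancer peaks
#'
#' Drops peaks classified as promoter or exon, retaining intronic and
#' intergenic peaks — the "putative enhancer" filter applied after
#' intersecting open-chromatin and H3K27Ac peaks.
#'
#' @inheritParams classify_peaks
#' @return The subset of `peaks` whose category is intron or intergenic,
#'   in input order.
#' @export
filter_enhancers <- function(peaks, gm, promoter_window = 1000) {
  if (!length(peaks)) return(peaks)
  ann <- classify_peaks(peaks, gm, promoter_window)
  peaks[ann$category %in% c("intron", "intergenic")]
}

#' Softly assign candidate enhancers to nearby TSSs
#'
#' Soft annotation: every gene whose TSS lies within `window` bp of the
#' element midpoint is attached (many-to-many linkage), each with a signed
#' distance (positive when the TSS is downstream of the midpoint in genome
#' coordinates). The midpoint is `floor((start + end) / 2)` in BED
#' coordinates and the window boundary is inclusive.
#'
#' @param cres `GRanges` of candidate cis-regulatory elements.
#' @param gm A [gene_models] object.
#' @param window Assignment window in bp (default 35000).
#' @return data.frame with columns `cre_id` (`chrom:start-end`), `gene_id`,
#'   `distance`, `gene_strand`; zero rows when nothing qualifies. Elements
#'   with no in-window TSS are absent.
#' @export
assign_to_tss <- function(cres, gm, window = 35000) {
  if (window <= 0) stop("window must be positive")
  empty <- data.frame(cre_id = character(0), gene_id = character(0),
                      distance = numeric(0), gene_strand = character(0))
  if (!length(cres) || !length(gm)) return(empty)
  cdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(cres)),
                    start = interval_start0(cres),
                    end = interval_end0(cres))
  cdf$cre_id <- cre_id(cres)
  cdf$mid <- floor((cdf$start + cdf$end) / 2)
  g <- gm$genes
  rows <- vector("list", nrow(cdf))
  for (i in seq_len(nrow(cdf))) {
    same <- g$chrom == cdf$chrom[i]
    if (!any(same)) next
    d <- g$tss[same] - cdf$mid[i]
    keep <- abs(d) <= window
    if (!any(keep)) next
    rows[[i]] <- data.frame(cre_id = cdf$cre_id[i],
                            gene_id = g$gene_id[same][keep],
                            distance = d[keep],
                            gene_strand = g$strand[same][keep])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$cre_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Stable element identifiers
#'
#' `chrom:start-end` in BED coordinates; the countable unit of the pipeline
#' (intersection fragments get fresh ids).
#'
#' @param gr A `GRanges`.
#' @return Character vector of ids.
#' @export
cre_id <- function(gr) {
  sprintf("%s:%s-%s", as.character(GenomicRanges::seqnames(gr)),
          format(interval_start0(gr), scientific = FALSE, trim = TRUE),
          format(interval_end0(gr), scientific = FALSE, trim = TRUE))
}
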