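#' Synthetic stand-in for a target/disease-locus association study
#'
#' The published association between putative targets and hereditary
#' hearing-loss loci rests on an OMIM extract and a genome-wide human gene
#' table that cannot be redistributed. This generator builds a synthetic
#' replacement with the same statistical structure: `n_loci` unresolved
#' loci on a toy multi-chromosome genome, `n_targets` target genes of
#' which exactly `n_in_loci` lie inside a locus, and a surrounding gene
#' universe partly inside loci. The overlap counts are then *recomputed*
#' from coordinates by [genes_in_loci] and [crossref_targets]; nothing is
#' read off the design.
#'
#' @param n_targets Number of target genes (default 156).
#' @param n_in_loci Targets placed inside loci (default 36).
#' @param n_loci Unresolved loci (default 50).
#' @param n_universe_in_loci Non-target universe genes inside loci.
#' @param n_universe_out Non-target universe genes outside loci.
#' @param seed Integer seed (jitters gene placement within their zones).
#' @return List with `gm` ([gene_models]), `loci` (unresolved locus
#'   data.frame), `sizes`, `targets` (character vector of target gene
#'   ids), `universe` (all gene ids) and `truth` (designed in-locus
#'   target ids).
#' @export
simulate_locus_study <- function(n_targets = 156, n_in_loci = 36,
                                 n_loci = 50, n_universe_in_loci = 100,
                                 n_universe_out = 900, seed = 1) {
  if (n_in_loci > n_targets) stop("n_in_loci cannot exceed n_targets")
  if (n_in_loci > n_loci) stop("need at least one locus per in-locus target")
  set.seed(seed)
  chrom_len <- 5e6
  loci_per_chrom <- 5
  n_chrom <- ceiling(n_loci / loci_per_chrom)
  sizes <- stats::setNames(rep(chrom_len, n_chrom),
                           sprintf("hs%02d", seq_len(n_chrom)))
  # loci tile each chromosome on a 900 kb period: locus [100k, 400k) then
  # a 600 kb gap; genes are placed well inside either zone so the 100 bp
  # flank never flips a designed membership
  locus_chrom <- rep(names(sizes), each = loci_per_chrom)[seq_len(n_loci)]
  locus_j <- rep(seq_len(loci_per_chrom) - 1, n_chrom)[seq_len(n_loci)]
  loci <- data.frame(locus_id = sprintf("DFN_%03d", seq_len(n_loci)),
                     chrom = locus_chrom,
                     start = 100000 + locus_j * 900000,
                     end = 400000 + locus_j * 900000,
                     causative_gene = NA_character_,
                     phenotype = "hearing loss (synthetic)")

  place <- function(ids, zone_start, zone_chrom) {
    span <- 4000
    start <- zone_start + round(stats::runif(length(ids), 0, 2000))
    data.frame(gene_id = ids, chrom = zone_chrom, strand = "+",
               tss = start, span_start = start, span_end = start + span)
  }
  genes <- list()
  # in-locus targets: one per locus, 100 kb inside the locus start
  tin <- sprintf("TGT%03d", seq_len(n_in_loci))
  genes[[1]] <- place(tin, loci$start[seq_len(n_in_loci)] + 100000,
                      loci$chrom[seq_len(n_in_loci)])
  # out-of-locus targets: in the inter-locus gaps, >= 50 kb from any locus
  tout <- sprintf("TGT%03d", n_in_loci + seq_len(n_targets - n_in_loci))
  slot <- seq_len(n_targets - n_in_loci) - 1
  gap_chrom <- names(sizes)[(slot %% n_chrom) + 1]
  gap_j <- (slot %/% n_chrom) %% loci_per_chrom
  gap_off <- 450000 + 30000 * (slot %/% (n_chrom * loci_per_chrom))
  genes[[2]] <- place(tout, gap_off + gap_j * 900000, gap_chrom)
  # non-target universe genes, inside and outside loci
  uin <- sprintf("UNI_IN%03d", seq_len(n_universe_in_loci))
  slot <- seq_len(n_universe_in_loci) - 1
  li <- (slot %% n_loci) + 1
  genes[[3]] <- place(uin, loci$start[li] + 150000 +
                        20000 * (slot %/% n_loci), loci$chrom[li])
  uout <- sprintf("UNI_OUT%03d", seq_len(n_universe_out))
  slot <- seq_len(n_universe_out) - 1
  gap_chrom <- names(sizes)[(slot %% n_chrom) + 1]
  gap_j <- (slot %/% n_chrom) %% loci_per_chrom
  gap_off <- 700000 + 12000 * (slot %/% (n_chrom * loci_per_chrom))
  if (max(gap_off) > 960000) stop("too many out-of-locus universe genes")
  genes[[4]] <- place(uout, gap_off + gap_j * 900000, gap_chrom)

  g <- do.call(rbind, genes)
  exons <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      start = g$span_start, end = g$span_end)
  gm <- gene_models(g, exons)
  list(gm = gm, loci = loci, sizes = sizes,
       targets = c(tin, tout), universe = g$gene_id,
       truth = list(in_locus_targets = tin,
                    in_locus_universe = c(tin, uin)))
}

#' Synthetic stand-in for a two-stage human expression table
#'
#' Emulates otic-vesicle-versus-hindbrain differential expression measured
#' at two embryonic stages for a set of ortholog genes: each "otic
#' enriched" gene passes the `log2fc > 1.5 & padj < 0.1` filter at stage 1,
#' stage 2 or both (pattern drawn at random), while the remaining genes
#' show higher expression in the reference tissue (negative fold change)
#' at both stages. Values are drawn away from the thresholds so membership
#' is unambiguous; the partition is recomputed from the values by
#' [de_filter], never read off the design.
#'
#' @param n_genes Number of ortholog genes (default 156).
#' @param n_enriched Genes enriched at stage 1 and/or stage 2
#'   (default 121).
#' @param seed Integer seed.
#' @return data.frame with columns `gene_id`, `stage1_log2fc`,
#'   `stage1_padj`, `stage2_log2fc`, `stage2_padj` and an attribute
#'   `truth` holding the designed enriched ids.
#' @export
simulate_stage_expression <- function(n_genes = 156, n_enriched = 121,
                                      seed = 1) {
  if (n_enriched > n_genes) stop("n_enriched cannot exceed n_genes")
  set.seed(seed)
  ids <- sprintf("TGT%03d", seq_len(n_genes))
  enriched <- seq_len(n_enriched)
  pattern <- sample(c("s1", "s2", "both"), n_enriched, replace = TRUE)
  pass_lfc <- function(n) stats::runif(n, 1.7, 5)
  pass_p <- function(n) stats::runif(n, 1e-4, 0.08)
  fail_lfc <- function(n) stats::runif(n, -4, -0.5)
  fail_p <- function(n) stats::runif(n, 1e-4, 0.9)
  s1_lfc <- fail_lfc(n_genes); s1_p <- fail_p(n_genes)
  s2_lfc <- fail_lfc(n_genes); s2_p <- fail_p(n_genes)
  p1 <- enriched[pattern != "s2"]
  p2 <- enriched[pattern != "s1"]
  s1_lfc[p1] <- pass_lfc(length(p1)); s1_p[p1] <- pass_p(length(p1))
  s2_lfc[p2] <- pass_lfc(length(p2)); s2_p[p2] <- pass_p(length(p2))
  out <- data.frame(gene_id = ids,
                    stage1_log2fc = round(s1_lfc, 4),
                    stage1_padj = signif(s1_p, 4),
                    stage2_log2fc = round(s2_lfc, 4),
                    stage2_padj = signif(s2_p, 4))
  attr(out, "truth") <- ids[enriched]
  out
}
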