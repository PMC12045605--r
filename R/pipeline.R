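#' Default run configuration
#'
#' All pipeline thresholds with their standard defaults: 35 kb assignment
#' window, motif p-value 0.001, expression enrichment FC > 2 and
#' FPKM > 10, differential-expression filter log2FC > 1.5 and padj < 0.1,
#' 100 bp locus flank, enrichment alpha 0.1, assay alpha 0.05, promoter
#' half-width 1000 bp, uniform background, pseudocount 0.001. Input paths
#' are NULL until supplied.
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    atac = NULL, h3k27ac = NULL, genes = NULL, genome = NULL, pwms = NULL,
    expression = NULL, orthologs = NULL, loci = NULL, chrom_sizes = NULL,
    de_table = NULL, qpcr = NULL,
    window = 35000, p_threshold = 0.001, fc_min = 2, fpkm_min = 10,
    lfc_min = 1.5, padj_max = 0.1, flank = 100, alpha_enrich = 0.1,
    alpha_assay = 0.05, promoter_window = 1000,
    background = rep(0.25, 4), pseudocount = 0.001,
    granularity = 1 / 1000, input_fraction = 0.01, seed = 1
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; absent keys take the defaults of
#' [default_run_config].
#'
#' @param path YAML file.
#' @return Named configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}

require_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) stop("config is missing required input: ", k)
    if (!file.exists(cfg[[k]])) stop("input file not found: ", cfg[[k]])
  }
}

write_manifest <- function(out_dir, stage, cfg, input_keys) {
  inputs <- lapply(cfg[input_keys], function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("cretargets")),
                   config = cfg[setdiff(names(cfg), input_keys)],
                   inputs = inputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; key by the first word
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Run one pipeline stage
#'
#' Stages: `call-targets` (full target identification), `scan-motifs`
#' (PWM scan of BED intervals), `annotate` (peak classification and TSS
#' assignment), `loci-enrich` (disease-locus cross-reference and
#' enrichment test), `chip-qpcr` (percent input and ratio paired t-tests
#' per region), `de-filter` (differential-expression threshold filter)
#' and `simulate` (synthetic study generation). Each stage writes its
#' result tables and a `manifest.json` recording the configuration and
#' input digests to `out_dir`, then returns its results invisibly.
#'
#' @param name Stage name.
#' @param config Configuration list (see [default_run_config] /
#'   [read_run_config]).
#' @param out_dir Output directory, created if needed.
#' @return The stage's result object, invisibly.
#' @export
run_stage <- function(name, config = default_run_config(), out_dir) {
  name <- match.arg(name, c("call-targets", "scan-motifs", "annotate",
                            "loci-enrich", "chip-qpcr", "de-filter",
                            "simulate"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  res <- switch(name,
    "simulate" = {
      study <- simulate_study(seed = cfg$seed,
                              config = simulation_config(),
                              out_dir = out_dir)
      write_manifest(out_dir, name, cfg, character(0))
      study
    },
    "call-targets" = {
      keys <- c("atac", "h3k27ac", "genes", "genome", "pwms", "expression")
      require_inputs(cfg, keys)
      gm <- read_gene_models(cfg$genes)
      genome <- read_genome_fasta(cfg$genome)
      sizes <- stats::setNames(Biostrings::width(genome), names(genome))
      atac <- read_bed(cfg$atac, sizes = sizes)
      k27 <- read_bed(cfg$h3k27ac, sizes = sizes)
      pwms <- read_meme(cfg$pwms, pseudocount = cfg$pseudocount)
      expr <- utils::read.table(cfg$expression, sep = "\t", header = TRUE)
      cres <- active_enhancers(atac, k27, gm,
                               promoter_window = cfg$promoter_window)
      calls <- call_targets(cres, gm, expr, pwms, genome,
                            window = cfg$window,
                            p_threshold = cfg$p_threshold,
                            fc_min = cfg$fc_min, fpkm_min = cfg$fpkm_min,
                            granularity = cfg$granularity)
      write_tsv(calls$targets, file.path(out_dir, "targets.tsv"))
      write_tsv(calls$cre_table, file.path(out_dir, "cres.tsv"))
      write_tsv(calls$hits, file.path(out_dir, "motif_hits.tsv"))
      write_manifest(out_dir, name, cfg, keys)
      calls
    },
    "scan-motifs" = {
      keys <- c("atac", "genome", "pwms")  # atac slot carries the BED here
      require_inputs(cfg, keys)
      genome <- read_genome_fasta(cfg$genome)
      sizes <- stats::setNames(Biostrings::width(genome), names(genome))
      ivs <- read_bed(cfg$atac, sizes = sizes)
      pwms <- read_meme(cfg$pwms, pseudocount = cfg$pseudocount)
      hits <- scan_intervals(ivs, genome, pwms,
                             p_threshold = cfg$p_threshold,
                             granularity = cfg$granularity)
      write_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
      write_manifest(out_dir, name, cfg, keys)
      hits
    },
    "annotate" = {
      keys <- c("atac", "genes")
      require_inputs(cfg, keys)
      gm <- read_gene_models(cfg$genes)
      peaks <- read_bed(cfg$atac)
      ann <- classify_peaks(peaks, gm,
                            promoter_window = cfg$promoter_window)
      keep <- genomic_intervals(ann$chrom, ann$start, ann$end)[
        ann$category %in% c("intron", "intergenic")]
      assign <- assign_to_tss(keep, gm, window = cfg$window)
      write_tsv(ann, file.path(out_dir, "peak_annotation.tsv"))
      write_tsv(assign, file.path(out_dir, "tss_assignment.tsv"))
      write_manifest(out_dir, name, cfg, keys)
      list(annotation = ann, assignment = assign)
    },
    "loci-enrich" = {
      keys <- c("loci", "genes", "orthologs")
      require_inputs(cfg, keys)
      gm <- read_gene_models(cfg$genes)
      loci <- read_disease_loci(cfg$loci)
      parts <- partition_loci(loci)
      # targets = mapped orthologs listed one per line in the expression
      # slot when provided, otherwise all mapped ids
      mapping <- utils::read.table(cfg$orthologs, sep = "\t", header = TRUE,
                                   colClasses = "character")
      targets <- map_orthologs(unique(mapping$source_id), mapping)$mapped
      in_loci <- genes_in_loci(gm, parts$unresolved, flank = cfg$flank)
      cr <- crossref_targets(targets, in_loci)
      universe <- gm$genes$gene_id
      enr <- fisher_enrichment(cr$k, cr$n,
                               K = length(intersect(universe, in_loci)),
                               N = length(universe),
                               alpha = cfg$alpha_enrich)
      summary <- list(k = enr$k, n = enr$n, K = enr$K, N = enr$N,
                      percentage = cr$percentage, p_value = enr$p_value,
                      alpha = enr$alpha, significant = enr$significant,
                      n_resolved = nrow(parts$resolved),
                      n_unresolved = nrow(parts$unresolved))
      write_tsv(data.frame(gene_id = cr$overlap),
                file.path(out_dir, "targets_in_loci.tsv"))
      jsonlite::write_json(summary, file.path(out_dir, "enrichment.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write_manifest(out_dir, name, cfg, keys)
      summary
    },
    "chip-qpcr" = {
      keys <- "qpcr"
      require_inputs(cfg, keys)
      tab <- utils::read.table(cfg$qpcr, sep = "\t", header = TRUE)
      res <- chip_qpcr_report(tab, input_fraction = cfg$input_fraction,
                              alpha = cfg$alpha_assay)
      write_tsv(res, file.path(out_dir, "chip_qpcr.tsv"))
      write_manifest(out_dir, name, cfg, keys)
      res
    },
    "de-filter" = {
      keys <- "de_table"
      require_inputs(cfg, keys)
      tab <- utils::read.table(cfg$de_table, sep = "\t", header = TRUE)
      ids <- de_filter(tab, lfc_min = cfg$lfc_min,
                       padj_max = cfg$padj_max)
      write_tsv(data.frame(gene_id = ids),
                file.path(out_dir, "de_enriched.tsv"))
      write_manifest(out_dir, name, cfg, keys)
      ids
    })
  invisible(res)
}

#' Per-region ChIP-qPCR report
#'
#' For each region, computes percent input for the specific antibody and
#' the IgG control across replicates and runs a one-tailed ratio paired
#' t-test of specific over control signal.
#'
#' @param tab data.frame with columns `region_id`, `replicate_id`,
#'   `ct_ip`, `ct_igg`, `ct_input`.
#' @param input_fraction Input chromatin fraction in (0, 1].
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per region: mean percent inputs, `t`,
#'   `df`, `p`, `significant`.
#' @export
chip_qpcr_report <- function(tab, input_fraction, alpha = 0.05) {
  need <- c("region_id", "replicate_id", "ct_ip", "ct_igg", "ct_input")
  stopifnot(all(need %in% names(tab)))
  do.call(rbind, lapply(split(tab, tab$region_id), function(r) {
    pi_ip <- percent_input(r$ct_ip, r$ct_input, input_fraction)
    pi_igg <- percent_input(r$ct_igg, r$ct_input, input_fraction)
    tt <- ratio_paired_ttest(pi_ip, pi_igg, tail = "one")
    data.frame(region_id = r$region_id[1], n = nrow(r),
               mean_percent_input_ip = mean(pi_ip),
               mean_percent_input_igg = mean(pi_igg),
               t = tt$t, df = tt$df, p = tt$p_value,
               indeterminate = tt$indeterminate,
               significant = !tt$indeterminate && tt$p_value <= alpha)
  }))
}
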