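#' Configuration for the synthetic study generator
#'
#' Defaults describe the standard toy study: 3 chromosomes of 100 kb,
#' 30 genes (10 per chromosome) of which 12 are expression-enriched,
#' 5 planted target genes, and all six decoy classes (ATAC-only peaks,
#' H3K27Ac-only peaks, promoter-overlapping elements, exonic elements,
#' motif-free active elements near enriched genes, and motif-bearing
#' elements near non-enriched genes).
#'
#' @param n_planted_targets Number of enriched genes that receive a
#'   motif-bearing element (0 to 5).
#' @param consensuses Consensus words of the three synthetic binding-site
#'   matrices.
#' @param information Per-position consensus probability of the matrices.
#' @param cre_width Width of each designed element in bp.
#' @param p_threshold Scan threshold the study is built to satisfy
#'   (element sequences are resampled until their hit content is exactly
#'   as designed at this threshold).
#' @param retry_cap Resampling attempts per element before giving up.
#' @return A named list of generator settings.
#' @export
simulation_config <- function(n_planted_targets = 5,
                              consensuses = c("TGATACGA", "CCATTAGC",
                                              "GAACGGTT"),
                              information = 0.97,
                              cre_width = 300,
                              p_threshold = 0.001,
                              retry_cap = 200) {
  if (n_planted_targets < 0 || n_planted_targets > 5) {
    stop("n_planted_targets must be between 0 and 5")
  }
  list(n_planted_targets = n_planted_targets, consensuses = consensuses,
       information = information, cre_width = cre_width,
       p_threshold = p_threshold, retry_cap = retry_cap,
       chrom_len = 100000L, window = 35000, promoter_window = 1000)
}

# fixed genomic layout of the toy study; all coordinates BED convention.
# Chromosome ends host planted-target genes (their elements sit ~4.3 kb
# from the TSS); chromosome middles host enriched non-target genes, always
# >= 35 kb from every motif-bearing element midpoint; chr3 carries no
# enriched gene except the left-end slot, so its right end can host
# motif-bearing decoy elements near non-enriched genes.
study_layout <- function() {
  gene <- function(id, chrom, tss, strand, enriched, role) {
    span_start <- if (strand == "+") tss else tss - 1999
    data.frame(gene_id = id, chrom = chrom, strand = strand, tss = tss,
               span_start = span_start, span_end = span_start + 2000,
               enriched = enriched, role = role)
  }
  genes <- rbind(
    gene("T1", "chr1", 8000, "+", TRUE, "target"),
    gene("T2", "chr1", 92000, "-", TRUE, "target"),
    gene("M1", "chr1", 44000, "+", TRUE, "enriched_bystander"),
    gene("M2", "chr1", 49000, "+", TRUE, "enriched_bystander"),
    gene("M3", "chr1", 54000, "+", TRUE, "enriched_bystander"),
    gene("F11", "chr1", 25000, "+", FALSE, "filler"),
    gene("F12", "chr1", 30000, "+", FALSE, "filler"),
    gene("F13", "chr1", 70000, "+", FALSE, "filler"),
    gene("F14", "chr1", 75000, "+", FALSE, "filler"),
    gene("F15", "chr1", 78000, "+", FALSE, "filler"),
    gene("T3", "chr2", 8000, "+", TRUE, "target"),
    gene("T4", "chr2", 92000, "-", TRUE, "target"),
    gene("M4", "chr2", 42000, "+", TRUE, "enriched_bystander"),
    gene("M5", "chr2", 47000, "+", TRUE, "enriched_bystander"),
    gene("M6", "chr2", 52000, "+", TRUE, "enriched_bystander"),
    gene("M7", "chr2", 57000, "+", TRUE, "enriched_bystander"),
    gene("F21", "chr2", 25000, "+", FALSE, "filler"),
    gene("F22", "chr2", 30000, "+", FALSE, "filler"),
    gene("F23", "chr2", 70000, "+", FALSE, "filler"),
    gene("F24", "chr2", 75000, "+", FALSE, "filler"),
    gene("T5", "chr3", 8000, "+", TRUE, "target"),
    gene("D1", "chr3", 92000, "-", FALSE, "decoy_motif_gene"),
    gene("D2", "chr3", 85000, "+", FALSE, "decoy_motif_gene"),
    gene("D3", "chr3", 80000, "+", FALSE, "decoy_motif_gene"),
    gene("F31", "chr3", 25000, "+", FALSE, "filler"),
    gene("F32", "chr3", 30000, "+", FALSE, "filler"),
    gene("F33", "chr3", 44000, "+", FALSE, "filler"),
    gene("F34", "chr3", 49000, "+", FALSE, "filler"),
    gene("F35", "chr3", 54000, "+", FALSE, "filler"),
    gene("F36", "chr3", 70000, "+", FALSE, "filler")
  )
  cre <- function(chrom, start, kind, gene_id = NA_character_) {
    data.frame(chrom = chrom, start = start, kind = kind, gene_id = gene_id)
  }
  # designed elements, 300 bp each; kind drives motif planting and truth
  cres <- rbind(
    cre("chr1", 3500, "planted", "T1"),
    cre("chr1", 96200, "planted", "T2"),
    cre("chr2", 3500, "planted", "T3"),
    cre("chr2", 96200, "planted", "T4"),
    cre("chr3", 3500, "planted", "T5"),
    cre("chr1", 46300, "motif_free"),   # near enriched bystanders
    cre("chr2", 45200, "motif_free"),
    cre("chr3", 58000, "motif_free"),
    cre("chr3", 96200, "decoy_motif", "D1"),  # near non-enriched genes only
    cre("chr3", 95600, "decoy_motif", "D2"),
    cre("chr3", 95000, "decoy_motif", "D3"),
    cre("chr1", 43900, "promoter_overlap"),   # inside M1 promoter zone
    cre("chr2", 46200, "promoter_overlap"),   # inside M5 promoter zone
    cre("chr1", 9450, "exonic"),              # inside T1 second exon
    cre("chr2", 90050, "exonic")              # inside T4 first exon
  )
  # peaks supported by one assay only (never intersect)
  atac_only <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                          start = c(60000, 62000, 64000))
  k27_only <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                         start = c(63000, 65000, 67000))
  loci <- data.frame(
    locus_id = c("R1", "R2", "R3", "U1", "U2", "U3"),
    chrom = c("chr1", "chr2", "chr3", "chr1", "chr2", "chr3"),
    start = c(7900, 41500, 79900, 24500, 89500, 53500),
    end = c(11100, 44600, 82100, 30500, 93500, 54200),
    causative_gene = c("T1", "M4", "D3", NA, NA, NA),
    phenotype = c("syndromic deafness", "syndromic deafness",
                  "non-syndromic deafness", "non-syndromic deafness",
                  "non-syndromic deafness", "non-syndromic deafness"))
  # genes whose spans overlap the 100 bp-extended unresolved loci, by design
  in_locus_genes <- c("F11", "F12", "T4", "F35")
  list(genes = genes, cres = cres, atac_only = atac_only,
       k27_only = k27_only, loci = loci, in_locus_genes = in_locus_genes)
}

random_dna <- function(n) {
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

# resample an element's background until its hit content is exactly as
# designed: planted elements carry one consensus site (all hits confined
# to it), motif-free elements carry none. Keeps ground truth exact at the
# configured threshold.
design_cre_seq <- function(width, pwms, dists, p_threshold, plant = NULL,
                           retry_cap = 200) {
  w_site <- if (is.null(plant)) 0L else nchar(plant$site)
  for (attempt in seq_len(retry_cap)) {
    s <- random_dna(width)
    if (!is.null(plant)) {
      off <- plant$offset  # 0-based within the element
      s <- paste0(substr(s, 1, off), plant$site,
                  substr(s, off + w_site + 1, width))
    }
    hits <- scan_multi(s, pwms, p_threshold = p_threshold, dists = dists)
    ok <- if (is.null(plant)) {
      nrow(hits) == 0
    } else {
      nrow(hits) >= 1 &&
        all(hits$start >= plant$offset &
            hits$end <= plant$offset + w_site) &&
        any(hits$pwm_name == plant$pwm_name & hits$start == plant$offset)
    }
    if (ok) return(s)
  }
  stop("could not realise the designed element after ", retry_cap,
       " attempts; enlarge the element or relax the design")
}

#' Generate a complete synthetic study
#'
#' Emits every input the pipeline consumes — genome, chromosome sizes,
#' gene models, ATAC and H3K27Ac peaks, binding-site matrices, expression
#' table, ortholog map and disease loci — together with the planted ground
#' truth. Background sequence is i.i.d. uniform over A/C/G/T (matching the
#' scanner's default background, so planted-site p-values are exactly
#' controlled); element sequences are resampled until their motif content
#' is exactly as designed. Regenerating with the same seed reproduces
#' byte-identical files.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param config See [simulation_config].
#' @param out_dir Optional directory; when given, all study files plus
#'   `truth.json` are written there (see [write_study]).
#' @return A list of class `synthetic_study` with elements `genome`
#'   (named `DNAStringSet`), `sizes`, `gm` ([gene_models]), `atac`,
#'   `h3k27ac` (`GRanges`), `pwms`, `expression`, `orthologs`, `loci`,
#'   `truth`, `config`, `seed`.
#' @export
simulate_study <- function(seed = 1, config = simulation_config(),
                           out_dir = NULL) {
  set.seed(seed)
  lay <- study_layout()
  width <- config$cre_width
  pwms <- lapply(seq_along(config$consensuses), function(i) {
    make_pwm(config$consensuses[i], information = config$information,
             name = sprintf("site_model_%d", i))
  })
  dists <- lapply(pwms, score_distribution)

  chroms <- c("chr1", "chr2", "chr3")
  sizes <- stats::setNames(rep(config$chrom_len, 3L), chroms)
  seqs <- lapply(sizes, random_dna)

  # planted targets: the first n_planted_targets of the five end slots get
  # a consensus site; the remaining slots become motif-free elements
  cres <- lay$cres
  planted_rows <- which(cres$kind == "planted")
  demote <- planted_rows[seq_len(5 - config$n_planted_targets) +
                           config$n_planted_targets]
  if (config$n_planted_targets < 5) {
    cres$kind[demote] <- "motif_free"
    cres$gene_id[demote] <- NA_character_
  }

  site_margin <- 20L
  cres$end <- cres$start + width
  for (i in seq_len(nrow(cres))) {
    kind <- cres$kind[i]
    if (kind %in% c("planted", "decoy_motif")) {
      p_idx <- (i - 1L) %% length(pwms) + 1L
      max_off <- width - nchar(config$consensuses[p_idx]) - site_margin
      plant <- list(site = config$consensuses[p_idx],
                    pwm_name = pwms[[p_idx]]$name,
                    offset = sample(site_margin:max_off, 1))
      s <- design_cre_seq(width, pwms, dists, config$p_threshold,
                          plant = plant, retry_cap = config$retry_cap)
    } else if (kind == "motif_free") {
      s <- design_cre_seq(width, pwms, dists, config$p_threshold,
                          plant = NULL, retry_cap = config$retry_cap)
    } else {
      next  # promoter/exonic decoys are filtered before scanning
    }
    chrom <- cres$chrom[i]
    seqs[[chrom]] <- paste0(substr(seqs[[chrom]], 1, cres$start[i]), s,
                            substr(seqs[[chrom]], cres$end[i] + 1,
                                   sizes[chrom]))
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))

  g <- lay$genes
  exons <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(gene_id = g$gene_id[i], chrom = g$chrom[i],
               start = c(g$span_start[i], g$span_end[i] - 600),
               end = c(g$span_start[i] + 600, g$span_end[i]))
  }))
  gm <- gene_models(g[, c("gene_id", "chrom", "strand", "tss",
                          "span_start", "span_end")], exons)

  # peak sets: each designed element is covered by an ATAC peak hanging
  # over its left edge and an H3K27Ac peak hanging over its right edge, so
  # their per-base intersection is exactly the element
  atac <- rbind(data.frame(chrom = cres$chrom, start = cres$start - 60,
                           end = cres$end),
                data.frame(chrom = lay$atac_only$chrom,
                           start = lay$atac_only$start,
                           end = lay$atac_only$start + 400))
  k27 <- rbind(data.frame(chrom = cres$chrom, start = cres$start,
                          end = cres$end + 60),
               data.frame(chrom = lay$k27_only$chrom,
                          start = lay$k27_only$start,
                          end = lay$k27_only$start + 400))
  atac_gr <- genomic_intervals(atac$chrom, atac$start, atac$end,
                               sizes = sizes)
  k27_gr <- genomic_intervals(k27$chrom, k27$start, k27$end, sizes = sizes)

  # expression: enriched genes pass FC > 2 & FPKM > 10; non-enriched fail
  # one criterion each (alternating), exercising both filter arms
  n <- nrow(g)
  fc <- numeric(n); fpkm <- numeric(n)
  fail_fc <- rep(c(TRUE, FALSE), length.out = sum(!g$enriched))
  j <- 1
  for (i in seq_len(n)) {
    if (g$enriched[i]) {
      fc[i] <- stats::runif(1, 2.5, 8)
      fpkm[i] <- stats::runif(1, 15, 80)
    } else if (fail_fc[j]) {
      fc[i] <- stats::runif(1, 0.3, 1.8)
      fpkm[i] <- stats::runif(1, 15, 80)
      j <- j + 1
    } else {
      fc[i] <- stats::runif(1, 2.5, 8)
      fpkm[i] <- stats::runif(1, 1, 9)
      j <- j + 1
    }
  }
  expression <- data.frame(gene_id = g$gene_id,
                           fold_change = round(fc, 4),
                           fpkm = round(fpkm, 4))

  orthologs <- data.frame(source_id = g$gene_id,
                          target_id = paste0("HS_", g$gene_id))
  orthologs <- orthologs[orthologs$source_id != "F36", ]  # one unmapped

  active_kinds <- c("planted", "motif_free", "decoy_motif")
  truth <- list(
    seed = seed,
    target_genes = sort(g$gene_id[g$role == "target" &
      g$gene_id %in% cres$gene_id[cres$kind == "planted"]]),
    planted_cres = sort(sprintf("%s:%d-%d",
      cres$chrom[cres$kind == "planted"],
      as.integer(cres$start[cres$kind == "planted"]),
      as.integer(cres$end[cres$kind == "planted"]))),
    active_cres = sort(sprintf("%s:%d-%d",
      cres$chrom[cres$kind %in% active_kinds],
      as.integer(cres$start[cres$kind %in% active_kinds]),
      as.integer(cres$end[cres$kind %in% active_kinds]))),
    enriched_genes = sort(g$gene_id[g$enriched]),
    in_locus_genes = sort(lay$in_locus_genes),
    n_unresolved_loci = sum(is.na(lay$loci$causative_gene)),
    n_resolved_loci = sum(!is.na(lay$loci$causative_gene)))

  study <- structure(list(genome = genome, sizes = sizes, gm = gm,
                          atac = atac_gr, h3k27ac = k27_gr, pwms = pwms,
                          expression = expression, orthologs = orthologs,
                          loci = lay$loci, truth = truth, config = config,
                          seed = seed),
                     class = "synthetic_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study (seed ", x$seed, "): ", length(x$genome),
      " chromosomes, ", length(x$gm), " genes, ",
      length(x$truth$target_genes), " planted target genes\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the exact formats the pipeline consumes (FASTA, chrom.sizes, gene
#' TSV, BED peak sets, MEME-minimal matrices, expression/ortholog/locus
#' TSVs) plus `truth.json`. Identical studies produce byte-identical
#' files.
#'
#' @param study A `synthetic_study`.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(study$genome, p("genome.fa"), width = 80)
  utils::write.table(data.frame(names(study$sizes), unname(study$sizes)),
                     p("chrom.sizes"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gene_models(study$gm, p("genes.tsv"))
  write_bed(study$atac, p("atac.bed"))
  write_bed(study$h3k27ac, p("h3k27ac.bed"))
  write_meme(study$pwms, p("pwms.meme"))
  utils::write.table(study$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$orthologs, p("orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  loci <- study$loci
  loci$causative_gene[is.na(loci$causative_gene)] <- ""
  utils::write.table(loci, p("loci.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(vapply(c("genome.fa", "chrom.sizes", "genes.tsv", "atac.bed",
                     "h3k27ac.bed", "pwms.meme", "expression.tsv",
                     "orthologs.tsv", "loci.tsv", "truth.json"), p, ""))
}
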