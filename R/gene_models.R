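#' Gene models: TSS, strand and exon structure
#'
#' A `gene_models` object holds one record per gene: identifier, chromosome,
#' strand, transcription start site (TSS) and exon spans. The TSS anchors
#' enhancer-to-gene assignment; exons and the gene span drive peak
#' classification. Coordinates are stored in BED convention (0-based
#' half-open; the TSS is a 0-based position).
#'
#' On the + strand the TSS equals the gene-span start; on the - strand it is
#' the last base of the span (`span_end - 1`).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tss` (0-based, may be NA to derive from strand and span),
#'   `span_start`, `span_end`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         genes$gene_id[which(duplicated(genes$gene_id))[1]])
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  # derive span from exons when absent
  if (!("span_start" %in% names(genes))) {
    sp <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
      data.frame(gene_id = e$gene_id[1], span_start = min(e$start),
                 span_end = max(e$end))
    }))
    genes <- merge(genes, sp, by = "gene_id", sort = FALSE)
  }
  # per-gene structural checks
  for (g in genes$gene_id) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    row <- genes[genes$gene_id == g, ]
    if (!nrow(e)) stop("gene ", g, " has no exons")
    if (any(e$chrom != row$chrom)) {
      stop("gene ", g, ": exon on a different chromosome than the gene")
    }
    if (any(e$start < row$span_start) || any(e$end > row$span_end)) {
      stop("gene ", g, ": exon outside the gene span")
    }
    e <- e[order(e$start, e$end), ]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("gene ", g, ": overlapping exons")
    }
  }
  derived_tss <- ifelse(genes$strand == "+", genes$span_start,
                        genes$span_end - 1)
  if (!("tss" %in% names(genes)) || all(is.na(genes$tss))) {
    genes$tss <- derived_tss
  } else {
    genes$tss <- ifelse(is.na(genes$tss), derived_tss, genes$tss)
    off <- which(genes$tss != derived_tss)
    if (length(off)) {
      stop("gene ", genes$gene_id[off[1]],
           ": tss does not match the strand-appropriate gene-span boundary")
    }
  }
  genes <- genes[order(genes$gene_id),
                 c("gene_id", "chrom", "strand", "tss",
                   "span_start", "span_end")]
  rownames(genes) <- NULL
  exons <- exons[order(exons$gene_id, exons$start, exons$end),
                 c("gene_id", "chrom", "start", "end")]
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
length.gene_models <- function(x) nrow(x$genes)

# GRanges views used by annotation; all built from BED-convention fields
gene_tss_gr <- function(gm) {
  g <- gm$genes
  genomic_intervals(g$chrom, g$tss, g$tss + 1, strand = g$strand,
                    name = g$gene_id)
}

gene_span_gr <- function(gm) {
  g <- gm$genes
  genomic_intervals(g$chrom, g$span_start, g$span_end, strand = g$strand,
                    name = g$gene_id)
}

gene_exon_gr <- function(gm) {
  e <- gm$exons
  genomic_intervals(e$chrom, e$start, e$end, name = e$gene_id)
}

# promoter zone [tss - w, tss + w) per gene, clamped at the origin
gene_promoter_gr <- function(gm, promoter_window) {
  g <- gm$genes
  genomic_intervals(g$chrom, pmax(0, g$tss - promoter_window),
                    g$tss + promoter_window, name = g$gene_id)
}

#' Read gene models from GTF or a minimal TSV dialect
#'
#' The TSV dialect has six tab-separated columns with a header:
#' `gene_id`, `chrom`, `strand`, `tss` (0-based; empty/NA to derive from
#' strand), `exon_starts`, `exon_ends` (comma-separated 0-based half-open
#' coordinates). GTF input (1-based closed, `gene`/`exon` features carrying
#' a `gene_id` attribute) is converted to the internal convention on read.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gtf"`.
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "gtf") {
    gtf <- rtracklayer::import(path, format = "gtf")
    type <- as.character(gtf$type)
    gid <- as.character(gtf$gene_id)
    ex <- gtf[type == "exon"]
    if (!length(ex)) stop("GTF has no exon features: ", path)
    exons <- data.frame(gene_id = as.character(ex$gene_id),
                        chrom = as.character(GenomicRanges::seqnames(ex)),
                        start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex))
    gn <- gtf[type == "gene"]
    if (length(gn)) {
      if (anyDuplicated(as.character(gn$gene_id))) {
        stop("duplicate gene_id: ",
             as.character(gn$gene_id)[duplicated(as.character(gn$gene_id))][1])
      }
      genes <- data.frame(gene_id = as.character(gn$gene_id),
                          chrom = as.character(GenomicRanges::seqnames(gn)),
                          strand = as.character(GenomicRanges::strand(gn)),
                          span_start = GenomicRanges::start(gn) - 1L,
                          span_end = GenomicRanges::end(gn))
    } else {
      genes <- do.call(rbind, lapply(split(seq_along(ex), exons$gene_id),
        function(i) data.frame(
          gene_id = exons$gene_id[i[1]],
          chrom = exons$chrom[i[1]],
          strand = as.character(GenomicRanges::strand(ex))[i[1]],
          span_start = min(exons$start[i]), span_end = max(exons$end[i]))))
    }
    return(gene_models(genes, exons))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  if (!all(need %in% names(df))) {
    stop("gene TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  }
  exons <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    s <- as.numeric(strsplit(df$exon_starts[i], ",")[[1]])
    e <- as.numeric(strsplit(df$exon_ends[i], ",")[[1]])
    if (length(s) != length(e)) {
      stop("gene ", df$gene_id[i], ": exon_starts/exon_ends length mismatch")
    }
    data.frame(gene_id = df$gene_id[i], chrom = df$chrom[i],
               start = s, end = e)
  }))
  genes <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                      strand = df$strand,
                      tss = suppressWarnings(as.numeric(df$tss)))
  gene_models(genes, exons)
}

#' Write gene models in the minimal TSV dialect
#'
#' @param gm A [gene_models] object.
#' @param path Output file.
#' @export
write_gene_models <- function(gm, path) {
  rows <- lapply(seq_len(nrow(gm$genes)), function(i) {
    g <- gm$genes[i, ]
    e <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               tss = format(g$tss, scientific = FALSE),
               exon_starts = paste(format(e$start, scientific = FALSE, trim = TRUE),
                                   collapse = ","),
               exon_ends = paste(format(e$end, scientific = FALSE, trim = TRUE),
                                 collapse = ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
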