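test_that("peak classification follows the fixed priority order", {
  gm <- toy_gene_models()
  # gA: chrA, + strand, tss 5000, exons [5000,5600) and [7200,8000)
  ann <- function(start, end, chrom = "chrA") {
    classify_peaks(genomic_intervals(chrom, start, end), gm)$category
  }
  expect_equal(ann(4900, 5100), "promoter")      # contains the TSS
  expect_equal(ann(7300, 7500), "exon")          # inside exon, > 1 kb from TSS
  expect_equal(ann(6500, 6700), "intron")        # inside span, between exons
  expect_equal(ann(20000, 20200), "intergenic")
  expect_equal(ann(8600, 8800, "chrB"), "promoter")  # minus-strand promoter
  # promoter priority over exon: peak covering TSS inside first exon
  expect_equal(ann(5000, 5200), "promoter")
})

test_that("classification matches a brute-force predicate oracle", {
  gm <- toy_gene_models()
  set.seed(21)
  df <- random_interval_df(200, chroms = c("chrA", "chrB"), len = 12000)
  got <- classify_peaks(df_to_gr(df), gm)
  g <- gm$genes
  for (i in seq_len(nrow(got))) {
    p <- got[i, ]
    ov <- function(s, e, chrom) p$chrom == chrom && p$start < e && s < p$end
    prom <- any(vapply(seq_len(nrow(g)), function(j)
      ov(max(0, g$tss[j] - 1000), g$tss[j] + 1000, g$chrom[j]), TRUE))
    exn <- any(vapply(seq_len(nrow(gm$exons)), function(j)
      ov(gm$exons$start[j], gm$exons$end[j], gm$exons$chrom[j]), TRUE))
    spn <- any(vapply(seq_len(nrow(g)), function(j)
      ov(g$span_start[j], g$span_end[j], g$chrom[j]), TRUE))
    want <- if (prom) "promoter" else if (exn) "exon" else
      if (spn) "intron" else "intergenic"
    expect_equal(got$category[i], want, info = paste("peak", i))
  }
})

test_that("enhancer filter keeps exactly the non-promoter non-exon peaks", {
  gm <- toy_gene_models()
  # 2 promoter, 2 exonic, 2 intronic, 2 intergenic peaks with known labels
  peaks <- genomic_intervals(
    rep("chrA", 8),
    c(4800, 5900, 7300, 5100, 6500, 6900, 15000, 18000),
    c(5200, 6100, 7400, 5300, 6600, 7100, 15400, 18400))
  out <- filter_enhancers(peaks, gm)
  expect_equal(sort(interval_start0(out)), c(6500, 6900, 15000, 18000))
  expect_length(filter_enhancers(genomic_intervals("chrA", 7300, 7400), gm), 0)
  # idempotent and a subset of the input
  expect_equal(gr_to_df(filter_enhancers(out, gm)), gr_to_df(out))
  far <- genomic_intervals("chrA", c(30000, 40000), c(30100, 40100))
  expect_equal(gr_to_df(filter_enhancers(far, gm)), gr_to_df(far))
})

test_that("empty gene set classifies everything intergenic with a warning", {
  gm <- toy_gene_models()
  gm$genes <- gm$genes[0, ]
  gm$exons <- gm$exons[0, ]
  expect_warning(
    ann <- classify_peaks(genomic_intervals("chrA", 0, 100), gm),
    "empty gene set")
  expect_equal(ann$category, "intergenic")
})

test_that("TSS assignment is soft, midpoint-based and boundary-inclusive", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = "+", tss = c(50000, 85001),
                      span_start = c(50000, 85001),
                      span_end = c(52000, 87001))
  exons <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(50000, 85001), end = c(52000, 87001))
  gm <- gene_models(genes, exons)
  # midpoint exactly at g1's TSS -> distance 0; g2 at 35001 bp -> excluded
  cre <- genomic_intervals("chr1", 49900, 50100)
  a <- assign_to_tss(cre, gm, window = 35000)
  expect_equal(a$gene_id, "g1")
  expect_equal(a$distance, 0)
  # one bp closer and the boundary becomes inclusive
  cre2 <- genomic_intervals("chr1", 49902, 50100)
  a2 <- assign_to_tss(cre2, gm, window = 35000)
  expect_setequal(a2$gene_id, c("g1", "g2"))
  expect_equal(a2$distance[a2$gene_id == "g2"], 35000)
  # no TSS in range -> element absent entirely
  expect_equal(nrow(assign_to_tss(genomic_intervals("chr2", 0, 100), gm)), 0)
})

test_that("assignment equals the exhaustive pairwise distance check", {
  set.seed(22)
  n_genes <- 10
  tss <- sort(sample.int(200000, n_genes))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                      strand = "+", tss = tss, span_start = tss,
                      span_end = tss + 500)
  exons <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                      start = tss, end = tss + 500)
  gm <- gene_models(genes, exons)
  starts <- sample.int(200000, 50)
  cres <- genomic_intervals("chr1", starts, starts + 300)
  got <- assign_to_tss(cres, gm, window = 35000)
  want <- 0L
  for (i in seq_along(cres)) {
    mid <- floor((interval_start0(cres)[i] + interval_end0(cres)[i]) / 2)
    for (j in seq_len(n_genes)) {
      d <- tss[j] - mid
      if (abs(d) <= 35000) {
        want <- want + 1L
        row <- got[got$cre_id == cre_id(cres[i]) &
                   got$gene_id == genes$gene_id[j], ]
        expect_equal(nrow(row), 1)
        expect_equal(row$distance, d)
      }
    }
  }
  expect_equal(nrow(got), want)
})

test_that("shrinking the window never adds assignments", {
  set.seed(23)
  n_genes <- 8
  tss <- sort(sample.int(100000, n_genes))
  genes <- data.frame(gene_id = sprintf("g%d", 1:n_genes), chrom = "chr1",
                      strand = "+", tss = tss, span_start = tss,
                      span_end = tss + 200)
  exons <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                      start = tss, end = tss + 200)
  gm <- gene_models(genes, exons)
  starts <- sample.int(100000, 30)
  cres <- genomic_intervals("chr1", starts, starts + 100)
  prev <- NULL
  for (w in c(5000, 15000, 35000, 60000)) {
    cur <- assign_to_tss(cres, gm, window = w)
    key <- paste(cur$cre_id, cur$gene_id)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})
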