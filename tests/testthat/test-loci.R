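test_that("loci are partitioned by causative-gene presence", {
  loci <- data.frame(locus_id = c("L1", "L2", "L3"),
                     chrom = "chr1", start = c(0, 100, 200),
                     end = c(50, 150, 250),
                     causative_gene = c("SIX1", NA, ""),
                     phenotype = "deafness")
  parts <- suppressMessages(partition_loci(loci))
  expect_equal(parts$resolved$locus_id, "L1")
  expect_equal(parts$unresolved$locus_id, c("L2", "L3"))
})

test_that("locus flank rescues genes just beyond the boundary", {
  # gene span [1050, 1300); locus ends at 1000
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      tss = 1050, span_start = 1050, span_end = 1300)
  exons <- data.frame(gene_id = "g", chrom = "chr1", start = 1050,
                      end = 1300)
  gm <- gene_models(genes, exons)
  locus <- function(end) data.frame(locus_id = "U", chrom = "chr1",
                                    start = 500, end = end,
                                    causative_gene = NA,
                                    phenotype = "x")
  # gene 50 bp beyond the locus end: flank 100 rescues it
  expect_equal(genes_in_loci(gm, locus(1000), flank = 100), "g")
  # gene 101 bp beyond: excluded (950 + 100 = 1050, half-open adjacency)
  expect_equal(genes_in_loci(gm, locus(950), flank = 100), character(0))
  # one bp more of flank and it re-enters
  expect_equal(genes_in_loci(gm, locus(950), flank = 101), "g")
})

test_that("genes_in_loci equals the exhaustive overlap oracle", {
  set.seed(51)
  tss <- sample.int(500000, 100)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                      strand = "+", tss = tss, span_start = tss,
                      span_end = tss + sample.int(5000, 100))
  exons <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                      start = genes$span_start, end = genes$span_end)
  gm <- gene_models(genes, exons)
  ls <- sample.int(480000, 10)
  loci <- data.frame(locus_id = sprintf("L%02d", 1:10), chrom = "chr1",
                     start = ls, end = ls + sample.int(20000, 10),
                     causative_gene = NA, phenotype = "x")
  flank <- 100
  got <- genes_in_loci(gm, loci, flank = flank)
  want <- character(0)
  for (i in 1:100) {
    for (j in 1:10) {
      if (genes$span_start[i] < loci$end[j] + flank &&
          loci$start[j] - flank < genes$span_end[i]) {
        want <- c(want, genes$gene_id[i])
      }
    }
  }
  expect_equal(got, sort(unique(want)))
  # monotone in the flank
  expect_true(all(genes_in_loci(gm, loci, flank = 0) %in% got))
  expect_true(all(got %in% genes_in_loci(gm, loci, flank = 5000)))
})

test_that("ortholog mapping de-duplicates and reports unmapped sources", {
  map <- data.frame(source_id = c("a", "b", "b"),
                    target_id = c("HA", "HB1", "HB2"))
  out <- suppressMessages(map_orthologs(c("a", "b", "c"), map))
  expect_equal(out$mapped, c("HA", "HB1", "HB2"))
  expect_equal(out$unmapped, "c")
  idm <- data.frame(source_id = c("x", "y"), target_id = c("x", "y"))
  expect_equal(map_orthologs(c("x", "y"), idm)$mapped, c("x", "y"))
})

test_that("fisher enrichment matches the closed-form example", {
  # N=10, K=5, n=4, k=4: C(5,4)*C(5,0)/C(10,4) = 5/210
  r <- fisher_enrichment(4, 4, 5, 10)
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(fisher_enrichment(0, 4, 5, 10)$p_value, 1, tolerance = 1e-12)
  expect_error(fisher_enrichment(5, 4, 5, 10), "inconsistent")
  expect_error(fisher_enrichment(2, 4, 11, 10), "inconsistent")
})

test_that("fisher enrichment equals exhaustive subset enumeration, N <= 12", {
  for (N in c(5, 8, 12)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, 3, N %/% 2)) {
        for (k in 0:min(n, K)) {
          if ((n - k) > (N - K)) next
          got <- fisher_enrichment(k, n, K, N)$p_value
          want <- oracle_hyper_upper(k, n, K, N)
          expect_equal(got, want, tolerance = 1e-9,
                       info = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
        }
      }
    }
  }
})

test_that("fisher enrichment equals the hypergeometric closed form at scale", {
  set.seed(52)
  for (rep in 1:20) {
    N <- sample(100:10000, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    kmax <- min(n, K)
    kmin <- max(0, n - (N - K))
    k <- sample(kmin:kmax, 1)
    got <- fisher_enrichment(k, n, K, N)$p_value
    want <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("fisher p-value is monotone non-increasing in k", {
  p <- vapply(0:8, function(k) fisher_enrichment(k, 8, 40, 100)$p_value, 1)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("crossref reports count and nearest-integer percentage", {
  expect_error(crossref_targets(character(0), "a"), "empty target set")
  out <- crossref_targets(c("a", "b"), c("c", "d"))
  expect_equal(out$k, 0)
  expect_equal(out$percentage, 0)
  out2 <- crossref_targets(c("a", "b"), c("a", "b", "c"))
  expect_equal(out2$percentage, 100)
  targets <- sprintf("t%03d", 1:156)
  out3 <- crossref_targets(targets, targets[1:36])
  expect_equal(out3$k, 36)
  expect_equal(out3$percentage, 23)
  # invariant to order of set operations
  out4 <- crossref_targets(rev(targets), sample(targets[1:36]))
  expect_equal(out4$k, out3$k)
  expect_equal(out4$overlap, out3$overlap)
})

test_that("disease-locus table round-trips through the TSV reader", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  st <- simulate_study(seed = 53)
  loci <- st$loci
  loci$causative_gene[is.na(loci$causative_gene)] <- ""
  utils::write.table(loci, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_disease_loci(tmp)
  expect_equal(back$locus_id, st$loci$locus_id)
  expect_equal(back$start, st$loci$start)
  expect_true(all(is.na(back$causative_gene[4:6])))
})
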