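# Independent brute-force oracles and tiny fixture builders shared by the
# suite. Oracles deliberately use per-base / per-word enumeration, never
# the interval or DP machinery they check.

# ---- interval oracles (plain data.frames of chrom/start/end, BED coords) --

random_interval_df <- function(n, chroms = c("chrA", "chrB"), len = 10000,
                               max_width = 400) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = pmin(start + width, len))
}

df_to_gr <- function(df) genomic_intervals(df$chrom, df$start, df$end)

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = interval_start0(gr), end = interval_end0(gr))
}

# mark every base covered by a and by b; emit maximal runs covered by both
oracle_intersect <- function(a, b, chroms, len) {
  out <- list()
  for (ch in sort(chroms)) {
    cov_a <- logical(len)
    cov_b <- logical(len)
    for (i in which(a$chrom == ch)) cov_a[(a$start[i] + 1):a$end[i]] <- TRUE
    for (i in which(b$chrom == ch)) cov_b[(b$start[i] + 1):b$end[i]] <- TRUE
    both <- cov_a & cov_b
    if (!any(both)) next
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep] - 1L,
                            end = ends[keep])
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

oracle_overlaps <- function(a1, b1) {
  # base-set intersection non-emptiness for two single intervals
  if (a1$chrom != b1$chrom) return(FALSE)
  length(intersect(seq(a1$start, a1$end - 1), seq(b1$start, b1$end - 1))) > 0
}

# ---- motif oracles ---------------------------------------------------------

random_pwm <- function(width, name = "rand", pseudocount = 0.001) {
  probs <- matrix(stats::rgamma(width * 4, shape = 1), ncol = 4)
  probs <- probs / rowSums(probs)
  pwm(probs, name = name, pseudocount = pseudocount)
}

# enumerate all 4^w words: integer score of each (on the distribution's
# grid) and its background probability
enumerate_words <- function(dist, background) {
  scores <- 0
  probs <- 1
  for (i in seq_len(nrow(dist$ints))) {
    scores <- as.vector(outer(scores, dist$ints[i, ], "+"))
    probs <- as.vector(outer(probs, background, "*"))
  }
  list(scores = scores, probs = probs)
}

# oracle survival values at every distinct achievable score
oracle_survival <- function(words) {
  o <- order(words$scores, decreasing = TRUE)
  s <- words$scores[o]
  cum <- cumsum(words$probs[o])
  last <- cumsum(rle(s)$lengths)
  list(scores = s[last], p = cum[last])
}

# per-window brute-force scorer used to cross-check scan_pwm
oracle_scan <- function(seq, x, p_threshold, dist) {
  chars <- strsplit(seq, "")[[1]]
  w <- pwm_width(x)
  hits <- list()
  for (st in c("+", "-")) {
    ints <- dist$ints
    if (st == "-") ints <- ints[rev(seq_len(w)), c(4, 3, 2, 1)]
    for (pos in seq_len(nchar(seq) - w + 1)) {
      word <- chars[pos:(pos + w - 1)]
      bi <- match(word, c("A", "C", "G", "T"))
      if (anyNA(bi)) next
      sc <- sum(ints[cbind(seq_len(w), bi)])
      p <- score_pvalue(dist, sc)
      if (p <= p_threshold) {
        hits[[length(hits) + 1]] <- data.frame(start = pos - 1L,
                                               end = pos - 1L + w,
                                               strand = st, p_value = p)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), p_value = numeric(0)))
  }
  res <- do.call(rbind, hits)
  res[order(res$start, res$strand), ]
}

# ---- fisher oracle ---------------------------------------------------------

# exhaustive enumeration over all n-subsets of an N-element universe with K
# marked elements: P(X >= k)
oracle_hyper_upper <- function(k, n, K, N) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # elements 1..K are the marked ones
  mean(hits >= k)
}

# ---- small fixtures --------------------------------------------------------

# two-chromosome toy gene set with known promoter/exon/intron/intergenic
# geometry (plus strand gene on chrA, minus strand gene on chrB)
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = c("chrA", "chrB"),
    strand = c("+", "-"),
    tss = c(5000, 8999),
    span_start = c(5000, 6000),
    span_end = c(8000, 9000))
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    chrom = c("chrA", "chrA", "chrB", "chrB"),
    start = c(5000, 7200, 6000, 8500),
    end = c(5600, 8000, 6400, 9000))
  gene_models(genes, exons)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
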