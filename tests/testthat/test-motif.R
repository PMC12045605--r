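test_that("log-odds scores are log2 probability ratios", {
  # zero pseudocount keeps the hand-computed values exact
  p <- pwm(matrix(0.25, 2, 4), pseudocount = 0)
  expect_equal(log_odds(p), matrix(0, 2, 4, dimnames = list(NULL, c("A", "C", "G", "T"))))
  p2 <- pwm(rbind(c(0.5, 0.25, 0.125, 0.125)), pseudocount = 0)
  expect_equal(as.numeric(log_odds(p2)), c(1, 0, -1, -1))
  # scaling probs and background identically leaves scores unchanged
  bg <- c(0.4, 0.1, 0.1, 0.4)
  p3 <- pwm(rbind(bg), background = bg, pseudocount = 0)
  expect_equal(as.numeric(log_odds(p3)), rep(0, 4))
})

test_that("width-1 score distribution equals enumeration of four bases", {
  p <- pwm(rbind(c(0.5, 0.25, 0.125, 0.125)), pseudocount = 0)
  d <- score_distribution(p)
  # scores 1, 0, -1, -1 bits at probability 1/4 each
  expect_equal(score_pvalue(d, round(1 / d$granularity)), 0.25)
  expect_equal(score_pvalue(d, 0), 0.5)
  expect_equal(score_pvalue(d, round(-1 / d$granularity)), 1)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
})

test_that("a background-equal PWM has the degenerate distribution p = 1", {
  p <- pwm(matrix(0.25, 3, 4), pseudocount = 0)
  d <- score_distribution(p)
  expect_equal(d$min, 0)
  expect_equal(d$max, 0)
  expect_equal(score_pvalue(d, 0), 1)
})

test_that("DP survival function equals exhaustive word enumeration", {
  set.seed(31)
  for (w in c(2, 4, 6, 8)) {
    x <- random_pwm(w)
    d <- score_distribution(x)
    words <- enumerate_words(d, x$background)
    oracle <- oracle_survival(words)
    expect_equal(score_pvalue(d, oracle$scores), oracle$p,
                 tolerance = 1e-9, info = paste("width", w))
  }
  # non-uniform background
  x <- pwm(random_pwm(5)$probs, background = c(0.3, 0.2, 0.2, 0.3),
           pseudocount = 0)
  d <- score_distribution(x)
  words <- enumerate_words(d, x$background)
  oracle <- oracle_survival(words)
  expect_equal(score_pvalue(d, oracle$scores), oracle$p, tolerance = 1e-9)
})

test_that("survival function is monotone and p(min score) = 1", {
  set.seed(32)
  x <- random_pwm(6)
  d <- score_distribution(x)
  expect_true(all(diff(d$sf) <= 1e-15))
  expect_equal(score_pvalue(d, d$min), 1)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
})

test_that("halving the granularity barely moves reported p-values", {
  set.seed(33)
  x <- make_pwm("TGATAC", information = 0.9)
  s <- paste0(random_seq(40), "TGATAC", random_seq(40))
  h1 <- scan_pwm(s, x, p_threshold = 0.01, granularity = 1 / 1000)
  h2 <- scan_pwm(s, x, p_threshold = 0.01, granularity = 1 / 2000)
  m <- merge(h1, h2, by = c("start", "strand"))
  expect_gt(nrow(m), 0)
  expect_equal(m$p_value.x, m$p_value.y, tolerance = 0.02)
})

test_that("an oversized discretised support is rejected with advice", {
  x <- random_pwm(8)
  expect_error(score_distribution(x, granularity = 1e-9),
               "coarser granularity")
})

test_that("scan finds a planted consensus as the unique sub-threshold hit", {
  set.seed(34)
  x <- make_pwm("TGATAC", information = 0.97)
  d <- score_distribution(x)
  repeat {  # background free of chance hits so the planted one is unique
    bg <- random_seq(200)
    if (nrow(scan_pwm(bg, x, p_threshold = 0.001, dist = d)) == 0) break
  }
  s <- paste0(substr(bg, 1, 20), "TGATAC", substr(bg, 27, 200))
  hits <- scan_pwm(s, x, p_threshold = 0.001, dist = d)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 20)
  expect_equal(hits$end, 26)
  expect_equal(hits$strand, "+")
  # brute-force window scoring agrees on every emitted hit
  oracle <- oracle_scan(s, x, 0.001, d)
  expect_equal(hits[, c("start", "end", "strand", "p_value")],
               oracle, ignore_attr = TRUE)
})

test_that("scan agrees with the brute-force window oracle, N windows skipped", {
  set.seed(35)
  x <- random_pwm(5)
  d <- score_distribution(x)
  s <- paste0(random_seq(60), "N", random_seq(60))
  got <- scan_pwm(s, x, p_threshold = 0.05, dist = d)
  oracle <- oracle_scan(s, x, 0.05, d)
  expect_equal(got[, c("start", "end", "strand", "p_value")], oracle,
               ignore_attr = TRUE)
  expect_false(any(got$start > 56 & got$start < 61))  # N straddled
})

test_that("reverse-complementing the sequence mirrors hits and strands", {
  set.seed(36)
  x <- make_pwm("TGACGT", information = 0.95)
  s <- paste0(random_seq(30), "TGACGT", random_seq(30), "ACGTCA",
              random_seq(30))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h <- scan_pwm(s, x, p_threshold = 0.001)
  hr <- scan_pwm(rc, x, p_threshold = 0.001)
  expect_equal(nrow(h), nrow(hr))
  L <- nchar(s)
  mirrored <- data.frame(start = L - h$end, end = L - h$start,
                         strand = ifelse(h$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(hr[, c("start", "end", "strand")], mirrored,
               ignore_attr = TRUE)
})

test_that("short and empty sequences give empty hit tables", {
  x <- make_pwm("TGATAC")
  expect_equal(nrow(scan_pwm("", x)), 0)
  expect_equal(nrow(scan_pwm("TGA", x)), 0)
})

test_that("hit count is monotone in the p-value threshold", {
  set.seed(37)
  x <- random_pwm(6)
  s <- random_seq(500)
  d <- score_distribution(x)
  ns <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 0.5),
               function(p) nrow(scan_pwm(s, x, p_threshold = p, dist = d)),
               1L)
  expect_true(all(diff(ns) >= 0))
  # every emitted hit satisfies its own threshold
  h <- scan_pwm(s, x, p_threshold = 0.01, dist = d)
  expect_true(all(h$p_value <= 0.01))
})

test_that("multi-PWM scan is the union of single scans", {
  set.seed(38)
  pwms <- list(make_pwm("TGATAC"), make_pwm("CCGGAA"), make_pwm("ATTGCA"))
  s <- paste0(random_seq(20), "TGATAC", random_seq(20), "CCGGAA",
              random_seq(20))
  multi <- scan_multi(s, pwms, p_threshold = 0.001)
  singles <- do.call(rbind, lapply(pwms, function(p)
    scan_pwm(s, p, p_threshold = 0.001)))
  singles <- singles[order(singles$start, singles$strand, singles$pwm_name), ]
  expect_equal(multi, singles, ignore_attr = TRUE)
  # identical PWMs under two names give duplicated hits, distinct names
  twins <- list(make_pwm("TGATAC", name = "a"), make_pwm("TGATAC", name = "b"))
  th <- scan_multi(s, twins, p_threshold = 0.001)
  expect_equal(sum(th$pwm_name == "a"), sum(th$pwm_name == "b"))
  expect_equal(nrow(scan_multi(s, pwms[1], p_threshold = 0.001)),
               nrow(scan_pwm(s, pwms[[1]], p_threshold = 0.001)))
})

test_that("motif deletion excises the lowest-p hit", {
  hits <- data.frame(sequence_id = "s", start = 3L, end = 9L, strand = "+",
                     pwm_name = "m", score = 5, p_value = 1e-4)
  out <- delete_motif("AAATGATACCC", hits)
  expect_equal(out$sequence, "AAACC")
  expect_equal(nchar(out$sequence), 11 - 6)
  two <- rbind(hits, data.frame(sequence_id = "s", start = 0L, end = 6L,
                                strand = "+", pwm_name = "m", score = 6,
                                p_value = 1e-5))
  out2 <- delete_motif("AAATGATACCC", two)
  expect_equal(out2$removed$p_value, 1e-5)
  expect_equal(out2$sequence, "TACCC")  # deletion at position 0
  expect_error(delete_motif("ACGT", hits[0, ]), "no motif to delete")
})

test_that("MEME minimal format round-trips within 1e-6", {
  set.seed(39)
  pwms <- lapply(1:3, function(i) random_pwm(3 + i, name = paste0("m", i)))
  tmp <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, tmp)
  # reading with zero pseudocount leaves the written probabilities as-is
  back <- read_meme(tmp, pseudocount = 0)
  expect_named(back, c("m1", "m2", "m3"))
  for (i in 1:3) {
    expect_equal(back[[i]]$probs, pwms[[i]]$probs, tolerance = 1e-6)
  }
  # uniform single motif
  writeLines(c("MEME version 4", "", "MOTIF uni",
               "letter-probability matrix: alength= 4 w= 2",
               "0.25 0.25 0.25 0.25", "0.25 0.25 0.25 0.25"), tmp)
  u <- read_meme(tmp, pseudocount = 0)
  expect_equal(u$uni$probs, matrix(0.25, 2, 4,
                                   dimnames = list(NULL, c("A", "C", "G", "T"))))
  # declared width disagreeing with the rows is an error
  writeLines(c("MEME version 4", "", "MOTIF bad",
               "letter-probability matrix: alength= 4 w= 3",
               "0.25 0.25 0.25 0.25"), tmp)
  expect_error(read_meme(tmp), "w= *3|declares")
  # a row that does not sum to one names the motif and row
  writeLines(c("MEME version 4", "", "MOTIF sums",
               "letter-probability matrix: alength= 4 w= 1",
               "0.9 0.2 0.1 0.1"), tmp)
  expect_error(read_meme(tmp), "sums.*row 1|row 1")
})

test_that("make_pwm builds the stated rows and rejects weak consensus", {
  p <- make_pwm("A", information = 0.97, pseudocount = 0)
  expect_equal(as.numeric(p$probs), c(0.97, 0.01, 0.01, 0.01))
  expect_error(make_pwm("ACGT", information = 0.25), "0.25")
  # near-uniform limit: maximal score tends to zero bits
  weak <- make_pwm("A", information = 0.2501, pseudocount = 0)
  expect_lt(max(log_odds(weak)), 0.001)
  # the consensus word of the default synthetic matrix is scannable at 1e-3
  x <- make_pwm("TGATAC", information = 0.97)
  d <- score_distribution(x)
  cons_score <- sum(d$ints[cbind(1:6, match(strsplit("TGATAC", "")[[1]], c("A", "C", "G", "T")))])
  expect_lt(score_pvalue(d, cons_score), 0.001)
})
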