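DNA <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A PWM is a width x 4 matrix of per-position base probabilities (columns
#' A, C, G, T) with a background distribution and a pseudocount. The
#' pseudocount is folded into the probabilities at construction
#' (`(p + c) / (1 + 4c)` per cell) so log-odds scores are always finite.
#'
#' @param probs Numeric width x 4 matrix; rows must sum to 1 within 1e-6
#'   before the pseudocount is applied.
#' @param name Motif name.
#' @param background Length-4 base probabilities, all strictly positive,
#'   summing to 1. Default uniform.
#' @param pseudocount Non-negative pseudocount, default 0.001.
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.001) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1) stop("PWM width must be >= 1")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("PWM '", name, "': row ",
         which(abs(rowSums(probs) - 1) > 1e-6)[1], " does not sum to 1")
  }
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  probs <- (probs + pseudocount) / (1 + 4 * pseudocount)
  dimnames(probs) <- list(NULL, DNA)
  structure(list(name = name, probs = probs,
                 background = as.numeric(background),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$name, "': width ", nrow(x$probs),
      ", consensus ", pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' @rdname pwm
#' @param x A `pwm`.
#' @export
pwm_width <- function(x) nrow(x$probs)

#' @rdname pwm
#' @export
pwm_consensus <- function(x) paste(DNA[max.col(x$probs)], collapse = "")

#' Log-odds score matrix in bits
#'
#' Entry (i, b) is `log2(probs[i, b] / background[b])`; a window's score is
#' the sum over positions of the entries of its bases.
#'
#' @param x A [pwm].
#' @return width x 4 numeric matrix (bits).
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (any(x$background <= 0)) stop("zero background probability")
  log2(sweep(x$probs, 2, x$background, "/"))
}

#' Exact null distribution of the PWM score
#'
#' Computes, by dynamic programming, the exact distribution of the
#' discretised log-odds score of a random word of motif width drawn from
#' the background: per-position scores are rounded to a grid of step
#' `granularity` (bits) and the probability mass function of their sum is
#' built by convolving one motif position at a time. The survival function
#' `P(score >= s)` converts any window score into an exact p-value under
#' the order-0 background null — the calibration behind the scan's
#' p-value threshold.
#'
#' The same integer grid is used when scoring scanned windows, so DP
#' p-values agree exactly with exhaustive enumeration over all `4^width`
#' words under the shared discretisation.
#'
#' @param x A [pwm].
#' @param granularity Discretisation step in bits (default 1/1000).
#' @param max_support Safety cap on the size of the discretised support;
#'   exceeding it raises an error advising a coarser granularity.
#' @return An object of class `score_distribution` with elements
#'   `granularity`, `ints` (integer score matrix), `min`/`max` (integer
#'   score bounds), `pmf` and `sf` (survival function, indexed from `min`).
#' @export
score_distribution <- function(x, granularity = 1 / 1000,
                               max_support = 2e7) {
  stopifnot(inherits(x, "pwm"))
  if (granularity <= 0) stop("granularity must be positive")
  lo <- log_odds(x)
  ints <- round(lo / granularity)
  lo_min <- sum(apply(ints, 1, min))
  lo_max <- sum(apply(ints, 1, max))
  support <- lo_max - lo_min + 1
  if (support > max_support) {
    stop("discretised score support (", support,
         ") exceeds the cap; use a coarser granularity")
  }
  # pmf over integer scores, offset so index 1 == current minimum sum
  pmf <- 1
  off <- 0  # integer score of index 1
  for (i in seq_len(nrow(ints))) {
    lo_i <- min(ints[i, ])
    hi_i <- max(ints[i, ])
    new <- numeric(length(pmf) + hi_i - lo_i)
    for (b in 1:4) {
      sh <- ints[i, b] - lo_i
      idx <- seq_along(pmf) + sh
      new[idx] <- new[idx] + pmf * x$background[b]
    }
    pmf <- new
    off <- off + lo_i
  }
  sf <- rev(cumsum(rev(pmf)))
  structure(list(granularity = granularity, ints = ints,
                 min = off, max = off + length(pmf) - 1,
                 pmf = pmf, sf = sf, name = x$name),
            class = "score_distribution")
}

#' P-value of a discretised score
#'
#' @param dist A [score_distribution].
#' @param int_score Integer score(s) on the distribution's grid (a window
#'   score is the sum of the per-position entries of `dist$ints`).
#' @return `P(score >= int_score)` under the background null; 1 at or below
#'   the minimum score.
#' @export
score_pvalue <- function(dist, int_score) {
  p <- numeric(length(int_score))
  below <- int_score <= dist$min
  above <- int_score > dist$max
  p[below] <- 1
  p[above] <- 0
  mid <- !below & !above
  p[mid] <- dist$sf[int_score[mid] - dist$min + 1]
  p
}

#' Build a sharply-peaked PWM from a consensus word
#'
#' Each position gives the consensus base the stated probability and splits
#' the remainder evenly over the other three bases. Used by the synthetic
#' study generator as a stand-in binding-site model whose planted sites are
#' guaranteed to pass a given p-value threshold.
#'
#' @param consensus Word over A/C/G/T.
#' @param information Per-position consensus probability in (0.25, 1);
#'   values at or below 0.25 are rejected (indistinguishable from uniform
#'   background).
#' @param name Motif name (default the consensus).
#' @param pseudocount Passed to [pwm].
#' @return A [pwm].
#' @export
make_pwm <- function(consensus, information = 0.97, name = consensus,
                     pseudocount = 0.001) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!length(bases) || !all(bases %in% DNA)) {
    stop("consensus must be a non-empty word over A/C/G/T")
  }
  if (information <= 0.25 || information >= 1) {
    stop("consensus probability must lie in (0.25, 1)")
  }
  probs <- matrix((1 - information) / 3, nrow = length(bases), ncol = 4)
  probs[cbind(seq_along(bases), match(bases, DNA))] <- information
  pwm(probs, name = name, pseudocount = pseudocount)
}
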