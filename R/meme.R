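#' Read and write PWMs in MEME minimal motif format
#'
#' The minimal format: a `MEME version` line, optional `ALPHABET=` and
#' `Background letter frequencies` sections, then one `MOTIF <name>` block
#' per matrix with a `letter-probability matrix:` header (`w=` width) and
#' one probability row per motif position (A C G T order). The background
#' is taken from the file when present, otherwise uniform.
#'
#' @param path File path.
#' @param pseudocount Pseudocount applied to every matrix read (see [pwm]).
#' @return `read_meme`: a named list of [pwm] objects.
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  if (!file.exists(path)) stop("MEME file not found: ", path)
  lines <- readLines(path)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    # frequencies may wrap over several lines until the next blank line
    j <- bg_at[1] + 1
    toks <- character(0)
    while (j <= length(lines) && nzchar(trimws(lines[j]))) {
      toks <- c(toks, strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1
    }
    if (length(toks) >= 8) {
      vals <- suppressWarnings(as.numeric(toks[seq(2, 8, by = 2)]))
      key <- toks[seq(1, 7, by = 2)]
      if (!any(is.na(vals)) && identical(toupper(key), DNA)) {
        background <- vals / sum(vals)
      }
    }
  }
  motif_at <- grep("^MOTIF\\s+", lines)
  if (!length(motif_at)) stop("no MOTIF blocks in ", path)
  pwms <- list()
  for (m in motif_at) {
    name <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    h <- m + 1
    while (h <= length(lines) && !grepl("^letter-probability matrix", lines[h])) {
      if (grepl("^MOTIF\\s+", lines[h])) break
      h <- h + 1
    }
    if (h > length(lines) || !grepl("^letter-probability matrix", lines[h])) {
      stop("motif '", name, "': missing letter-probability matrix header")
    }
    wdecl <- regmatches(lines[h], regexec("w=\\s*(\\d+)", lines[h]))[[1]]
    if (length(wdecl) < 2) stop("motif '", name, "': no w= in matrix header")
    w <- as.integer(wdecl[2])
    rows <- list()
    j <- h + 1
    while (j <= length(lines)) {
      tl <- trimws(lines[j])
      if (!nzchar(tl) || grepl("^(MOTIF|URL)", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (length(vals) != 4 || any(is.na(vals))) {
        stop("motif '", name, "': malformed probability row at line ", j)
      }
      rows[[length(rows) + 1]] <- vals
      j <- j + 1
    }
    if (length(rows) != w) {
      stop("motif '", name, "': header declares w=", w, " but ",
           length(rows), " rows found")
    }
    probs <- do.call(rbind, rows)
    bad <- which(abs(rowSums(probs) - 1) > 1e-3)
    if (length(bad)) {
      stop("motif '", name, "': row ", bad[1], " does not sum to 1")
    }
    probs <- probs / rowSums(probs)
    pwms[[name]] <- pwm(probs, name = name, background = background,
                        pseudocount = pseudocount)
  }
  pwms
}

#' @rdname read_meme
#' @param pwms List of [pwm] objects.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$probs)), con)
    # probabilities already include the construction pseudocount; written
    # at 10 significant digits so the round trip is well within 1e-6
    writeLines(apply(p$probs, 1, function(r)
      paste(sprintf("%.10f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
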