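#' Position weight matrix over {A,C,G,T}
#'
#' Probability matrix with one column per motif position (columns sum to 1)
#' and a background distribution. Cells below `1e-4` are floored at that
#' pseudo-probability (and columns renormalized) before log-odds scoring, so
#' sharp matrices never produce -Inf scores.
#'
#' @param mat 4 x w numeric matrix, rows A, C, G, T, columns summing to 1.
#' @param background length-4 probabilities summing to 1 (default uniform).
#' @param name motif name.
#' @return A `Pwm` object.
#' @export
pwm <- function(mat, background = rep(0.25, 4), name = "motif") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("pwm: matrix must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(mat) < 4) stop("pwm: motif width must be >= 4", call. = FALSE)
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    stop("pwm: each column must sum to 1", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9) {
    stop("pwm: background must sum to 1", call. = FALSE)
  }
  rownames(mat) <- c("A", "C", "G", "T")
  out <- list(name = name, mat = mat, background = as.numeric(background))
  class(out) <- "Pwm"
  out
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm '%s' (width %d), consensus %s\n", x$name, ncol(x$mat),
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus word of a PWM (highest-probability base per column)
#' @param x a [pwm()].
#' @return character string of length `width`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
}

# 5 x w log2-odds matrix with smoothing; 5th row (N) scores 0 = background
pwm_logodds <- function(x, smooth = 1e-4) {
  m <- pmax(x$mat, smooth)
  m <- sweep(m, 2, colSums(m), "/")
  lo <- log2(m / x$background)
  rbind(lo, N = 0)
}

#' Maximum achievable log-odds score of a PWM
#' @param x a [pwm()].
#' @return numeric scalar, the score of the best possible match.
#' @export
pwm_max_score <- function(x) {
  lo <- pwm_logodds(x)[1:4, , drop = FALSE]
  sum(apply(lo, 2, max))
}

#' Default score threshold: a fraction of the maximum achievable score
#' @param x a [pwm()].
#' @param fraction fraction of [pwm_max_score()] (default 0.6).
#' @return numeric threshold on the log-odds scale.
#' @export
pwm_score_threshold <- function(x, fraction = 0.6) {
  fraction * pwm_max_score(x)
}

# reverse-complemented PWM: reverse columns, swap A<->T, C<->G
pwm_revcomp <- function(x) {
  m <- x$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(x$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(m, background = x$background[c(4, 3, 2, 1)], name = x$name)
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses the "MEME version" minimal text format: background letter
#' frequencies plus one letter-probability matrix per MOTIF block.
#'
#' @param path file path.
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    toks <- strsplit(lines[bgi[1] + 1], "\\s+")[[1]]
    if (length(toks) >= 8) {
      bg <- as.numeric(toks[c(2, 4, 6, 8)])
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("read_meme: no MOTIF blocks in ", path, call. = FALSE)
  out <- list()
  for (s in starts) {
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    hi <- grep("^letter-probability matrix", lines)
    h <- hi[hi > s][1]
    if (is.na(h)) stop("read_meme: motif '", name, "' has no matrix", call. = FALSE)
    w <- as.numeric(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- t(vapply(strsplit(rows, "\\s+"),
                  function(tk) as.numeric(tk[1:4]), numeric(4)))
    out[[name]] <- pwm(t(m), background = bg, name = name)
  }
  out
}

#' Write motifs to a MEME minimal-format file
#'
#' @param pwms a [pwm()] or list of them.
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "Pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(p$mat)), con)
    for (j in seq_len(ncol(p$mat))) {
      writeLines(sprintf("%.6f %.6f %.6f %.6f", p$mat[1, j], p$mat[2, j],
                         p$mat[3, j], p$mat[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Built-in motif models used by the synthetic genome
#'
#' Sharply informative PWMs emulating an ETS-family core (GGAA, as bound by
#' ELF5), a forkhead motif (FOXA1) and an estrogen-response half-site-like
#' palindrome (ER). Each column puts probability `sharpness` on the
#' consensus base and splits the rest evenly.
#'
#' @param sharpness consensus-base probability per column (default 0.85).
#' @return Named list of [pwm()]s: `ETS`, `FKH`, `ERE`.
#' @export
builtin_pwms <- function(sharpness = 0.85) {
  mk <- function(word, name) {
    bases <- strsplit(word, "")[[1]]
    m <- matrix((1 - sharpness) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(bases)) m[bases[j], j] <- sharpness
    pwm(m, name = name)
  }
  list(ETS = mk("ACCGGAAGTA", "ETS"),
       FKH = mk("TGTTTACTTA", "FKH"),
       ERE = mk("AGGTCACAGTGACCT", "ERE"))
}
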