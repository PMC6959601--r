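# encode a DNA string as integer indices 1..5 (A,C,G,T,N/other)
encode_dna <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  idx <- rep(5L, length(v))
  idx[v == utf8ToInt("A")] <- 1L
  idx[v == utf8ToInt("C")] <- 2L
  idx[v == utf8ToInt("G")] <- 3L
  idx[v == utf8ToInt("T")] <- 4L
  idx
}

# log-odds scores for every offset of one strand; idx: encoded sequence
scan_scores <- function(idx, lo) {
  w <- ncol(lo)
  noff <- length(idx) - w + 1
  if (noff < 1) return(numeric(0))
  sc <- numeric(noff)
  for (j in seq_len(w)) {
    sc <- sc + lo[idx[j:(j + noff - 1)], j]
  }
  sc
}

#' Best PWM hit in a sequence (both strands)
#'
#' Scores every window of width `w` on both strands with the log2-odds of
#' PWM vs background; `N` bases contribute 0 (background probability). Ties
#' are broken to the leftmost offset, then to the + strand.
#'
#' @param sequence a DNA string (alphabet ACGTN, case-insensitive).
#' @param x a [pwm()].
#' @return List with `offset` (0-based window start), `strand` ("+"/"-") and
#'   `score` (log2 odds).
#' @export
log_odds_scan <- function(sequence, x) {
  idx <- encode_dna(sequence)
  w <- ncol(x$mat)
  if (length(idx) < w) {
    stop("log_odds_scan: sequence shorter than motif width", call. = FALSE)
  }
  fwd <- scan_scores(idx, pwm_logodds(x))
  rev <- scan_scores(idx, pwm_logodds(pwm_revcomp(x)))
  best <- max(fwd, rev)
  # leftmost offset wins; at the same offset "+" wins ties
  cand_f <- which(fwd >= best - 1e-12)
  cand_r <- which(rev >= best - 1e-12)
  of <- if (length(cand_f)) cand_f[1] else Inf
  or <- if (length(cand_r)) cand_r[1] else Inf
  if (of <= or) {
    list(offset = unname(of) - 1L, strand = "+", score = unname(fwd[of]))
  } else {
    list(offset = unname(or) - 1L, strand = "-", score = unname(rev[or]))
  }
}

# pull the sequence of [start, end) (0-based half-open) from a DNAStringSet
fetch_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not in genome FASTA", call. = FALSE)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1, end))
}

#' Load a genome FASTA as a DNAStringSet keyed by chromosome name
#' @param path FASTA path (or an already-loaded `DNAStringSet`).
#' @return `DNAStringSet`.
#' @export
load_genome <- function(path) {
  if (methods::is(path, "DNAStringSet")) return(path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*", "", names(g))
  g
}

#' Positional centrality profile of motif hits around peak summits
#'
#' For each peak, the best hit of each PWM within `half_window` bp of the
#' summit is located; hits scoring at least `score_min` are binned by the
#' offset of the hit's center from the summit. By default all curves are
#' normalized jointly so that the grand total probability mass over every
#' motif is 1 (`normalize = "joint"`); `"per_motif"` normalizes each curve
#' to 1 instead.
#'
#' @param peaks a [peak_set()].
#' @param genome FASTA path or `DNAStringSet`.
#' @param pwms list of [pwm()]s.
#' @param half_window bp on each side of the summit (default 250).
#' @param score_min log-odds threshold; default 60% of each PWM's maximum
#'   achievable score ([pwm_score_threshold()]).
#' @param bin_width offset bin width in bp (default 10).
#' @param normalize `"joint"` (default) or `"per_motif"`.
#' @return data.frame `(motif, offset_bin, mass)`; attribute `n_hits` gives
#'   hits passing threshold per motif. If no hit passes anywhere the profile
#'   is empty (total mass 0) and a warning is raised.
#' @export
positional_distribution <- function(peaks, genome, pwms, half_window = 250,
                                    score_min = NULL, bin_width = 10,
                                    normalize = c("joint", "per_motif")) {
  normalize <- match.arg(normalize)
  genome <- load_genome(genome)
  if (is.null(names(pwms))) names(pwms) <- vapply(pwms, `[[`, "", "name")
  sm <- summit_pos(peaks)
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  hits <- lapply(names(pwms), function(nm) {
    p <- pwms[[nm]]
    thr <- if (is.null(score_min)) pwm_score_threshold(p) else score_min
    w <- ncol(p$mat)
    offs <- numeric(0)
    for (i in seq_len(nrow(peaks))) {
      ch <- peaks$chrom[i]
      lo <- max(0, sm[i] - half_window)
      hi <- min(chrlen[[ch]], sm[i] + half_window)
      if (hi - lo < w) next
      s <- fetch_seq(genome, ch, lo, hi)
      h <- log_odds_scan(s, p)
      if (h$score >= thr) {
        offs <- c(offs, lo + h$offset + floor(w / 2) - sm[i])
      }
    }
    offs
  })
  names(hits) <- names(pwms)
  n_hits <- vapply(hits, length, 1L)
  if (sum(n_hits) == 0) {
    warning("positional_distribution: no hit passed the score threshold")
    out <- data.frame(motif = character(0), offset_bin = numeric(0),
                      mass = numeric(0))
    attr(out, "n_hits") <- n_hits
    return(out)
  }
  tab <- do.call(rbind, lapply(names(hits), function(nm) {
    if (!length(hits[[nm]])) return(NULL)
    b <- floor(hits[[nm]] / bin_width + 0.5) * bin_width
    cnt <- table(b)
    data.frame(motif = nm, offset_bin = as.numeric(names(cnt)),
               mass = as.numeric(cnt), stringsAsFactors = FALSE)
  }))
  if (normalize == "joint") {
    tab$mass <- tab$mass / sum(tab$mass)
  } else {
    tot <- stats::ave(tab$mass, tab$motif, FUN = sum)
    tab$mass <- tab$mass / tot
  }
  tab <- tab[order(tab$motif, tab$offset_bin), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_hits") <- n_hits
  tab
}

#' Fraction of peaks containing a motif hit
#'
#' Scans the sequence under each peak interval and reports the fraction
#' whose best hit reaches `score_min`.
#'
#' @param peaks a non-empty [peak_set()].
#' @param genome FASTA path or `DNAStringSet`.
#' @param x a [pwm()].
#' @param score_min log-odds threshold (default [pwm_score_threshold()]).
#' @return List `numerator`, `denominator`, `rate`.
#' @export
motif_presence_rate <- function(peaks, genome, x, score_min = NULL) {
  if (!nrow(peaks)) stop("motif_presence_rate: empty PeakSet", call. = FALSE)
  genome <- load_genome(genome)
  if (is.null(score_min)) score_min <- pwm_score_threshold(x)
  w <- ncol(x$mat)
  hit <- vapply(seq_len(nrow(peaks)), function(i) {
    if (peaks$end[i] - peaks$start[i] < w) return(FALSE)
    s <- fetch_seq(genome, peaks$chrom[i], peaks$start[i], peaks$end[i])
    log_odds_scan(s, x)$score >= score_min
  }, logical(1))
  list(numerator = sum(hit), denominator = nrow(peaks),
       rate = sum(hit) / nrow(peaks))
}
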