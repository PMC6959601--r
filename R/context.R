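#' Labeled annotation track
#'
#' An annotation class (repeat family, enhancer, super enhancer, HOT region,
#' open chromatin, ...) is just a [peak_set()] whose `set_name` carries the
#' label.
#'
#' @param intervals a [peak_set()].
#' @param label annotation label.
#' @return The PeakSet with `set_name` set to `label`.
#' @export
annotation_track <- function(intervals, label) {
  if (!nzchar(label)) stop("annotation_track: empty label", call. = FALSE)
  attr(intervals, "set_name") <- label
  intervals
}

# number of peaks overlapping >= 1 bp of the annotation
n_overlapping <- function(peaks, annotation) {
  if (!nrow(peaks) || !nrow(annotation)) return(0L)
  # disjoint chromosome sets are a legitimate zero-overlap case
  sum(suppressWarnings(
    GenomicRanges::countOverlaps(ps_granges(peaks), ps_granges(annotation))) > 0)
}

#' Odds ratio for annotation overlap of a focus set vs a background set
#'
#' Counts peaks (the counting unit) overlapping the annotation in the focus
#' and in an explicit background/universe set, forms the 2x2 table
#' `(a, b; c, d) = (focus&annot, focus-annot; bg&annot, bg-annot)` and
#' reports `OR = ad/bc` with a Haldane-Anscombe +0.5 applied to all cells
#' iff any cell is zero, the Woolf standard error of log OR
#' `sqrt(1/a+1/b+1/c+1/d)` on the (corrected) cells, a 95% CI, and the
#' two-sided Fisher exact p-value (tail-probability summation) on the
#' uncorrected table. There is no silent genome-wide default background: an
#' odds ratio is meaningless without a stated universe.
#'
#' @param focus,background non-empty [peak_set()]s; `background` may contain
#'   the focus peaks.
#' @param annotation an [annotation_track()] / PeakSet.
#' @return An `OddsRatioResult` list: `label`, `a`, `b`, `c`, `d`, `or`,
#'   `log_or_se`, `ci95`, `p`, `corrected`.
#' @export
odds_ratio_overlap <- function(focus, annotation, background) {
  if (!nrow(focus) || !nrow(background)) {
    stop("odds_ratio_overlap: focus and background must be non-empty",
         call. = FALSE)
  }
  a <- n_overlapping(focus, annotation)
  b <- nrow(focus) - a
  c_ <- n_overlapping(background, annotation)
  d <- nrow(background) - c_
  cells <- c(a, b, c_, d)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
  structure(list(label = attr(annotation, "set_name") %||% "annotation",
                 a = a, b = b, c = c_, d = d, or = or, log_or_se = se,
                 ci95 = ci, p = p, corrected = corrected),
            class = "OddsRatioResult")
}

#' @export
print.OddsRatioResult <- function(x, ...) {
  cat(sprintf(
    "OR[%s] = %.3f (95%% CI %.3f-%.3f), p = %.3g  [a=%d b=%d c=%d d=%d]%s\n",
    x$label, x$or, x$ci95[1], x$ci95[2], x$p, x$a, x$b, x$c, x$d,
    if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Odds-ratio profile over widening windows around summits
#'
#' Each focus and background peak is replaced by `summit +/- window/2`
#' (clipped at zero) and [odds_ratio_overlap()] is applied per window,
#' revealing whether annotation enrichment is local to the binding sites or
#' regional.
#'
#' @param peaks,background [peak_set()]s.
#' @param annotation an [annotation_track()].
#' @param windows ascending window widths in bp.
#' @return data.frame with one row per window (`window, a, b, c, d, or,
#'   log_or_se, ci_lo, ci_hi, p`).
#' @export
windowed_profile <- function(peaks, annotation, windows, background) {
  if (any(windows <= 0)) stop("windowed_profile: windows must be > 0", call. = FALSE)
  if (is.unsorted(windows)) stop("windowed_profile: windows must be ascending", call. = FALSE)
  expand <- function(ps, w) {
    s <- summit_pos(ps)
    peak_set(ps$chrom, pmax(0, s - floor(w / 2)), s + ceiling(w / 2),
             name = ps$name, set_name = attr(ps, "set_name"))
  }
  rows <- lapply(windows, function(w) {
    r <- odds_ratio_overlap(expand(peaks, w), annotation, expand(background, w))
    data.frame(window = w, a = r$a, b = r$b, c = r$c, d = r$d, or = r$or,
               log_or_se = r$log_or_se, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               p = r$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of peaks overlapping an annotation
#'
#' Reports the exact fraction and the integer percent with round-half-up
#' (so 139 of 503 = 27.63% prints as 28%).
#'
#' @param peaks a non-empty [peak_set()].
#' @param annotation an [annotation_track()].
#' @return List `numerator`, `denominator`, `percent` (exact) and
#'   `percent_int` (round-half-up integer).
#' @export
fraction_overlapping <- function(peaks, annotation) {
  if (!nrow(peaks)) stop("fraction_overlapping: empty PeakSet", call. = FALSE)
  num <- n_overlapping(peaks, annotation)
  den <- nrow(peaks)
  pct <- 100 * num / den
  list(numerator = num, denominator = den, percent = pct,
       percent_int = round_half_up(pct))
}

# round halves away from zero (R's round() goes half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Chi-squared test for overlap of two gained-site sets over a universe
#'
#' Universe regions are cross-classified by whether they overlap set A and
#' set B; the association is tested with Pearson's chi-squared (df = 1,
#' no continuity correction, appropriate for the large-count regime).
#'
#' @param gained_a,gained_b [peak_set()]s; every member should overlap some
#'   universe region (violations raise an error).
#' @param universe a [peak_set()] of regions forming the counting universe.
#' @return List `statistic`, `p`, `table` (2x2 counts), `n`.
#' @export
cistrome_overlap_test <- function(gained_a, gained_b, universe) {
  for (nm in c("gained_a", "gained_b")) {
    s <- get(nm)
    if (nrow(s) && any(GenomicRanges::countOverlaps(ps_granges(s),
                                                    ps_granges(universe)) == 0)) {
      stop("cistrome_overlap_test: some ", nm,
           " peaks overlap no universe region", call. = FALSE)
    }
  }
  inA <- GenomicRanges::countOverlaps(ps_granges(universe), ps_granges(gained_a)) > 0
  inB <- GenomicRanges::countOverlaps(ps_granges(universe), ps_granges(gained_b)) > 0
  if (!any(inA) || all(inA) || !any(inB) || all(inB)) {
    stop("cistrome_overlap_test: degenerate margin (a set is empty on, or covers, the universe)",
         call. = FALSE)
  }
  tab <- table(factor(inA, c(TRUE, FALSE)), factor(inB, c(TRUE, FALSE)))
  n <- sum(tab)
  tb <- matrix(as.numeric(tab), 2)  # numeric: counts overflow integers
  stat <- n * (tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1])^2 /
    (sum(tb[1, ]) * sum(tb[2, ]) * sum(tb[, 1]) * sum(tb[, 2]))
  list(statistic = as.numeric(stat),
       p = stats::pchisq(as.numeric(stat), df = 1, lower.tail = FALSE),
       table = unclass(tab), n = n)
}

#' Write a set of OddsRatioResults as TSV
#'
#' @param results list of `OddsRatioResult` (or a [windowed_profile()]
#'   data.frame, written as is).
#' @param path output path.
#' @export
write_odds_ratios <- function(results, path) {
  if (is.data.frame(results)) {
    utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$label, a = r$a, b = r$b, c = r$c, d = r$d, or = r$or,
               log_or_se = r$log_or_se, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               p = r$p, corrected = r$corrected)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
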