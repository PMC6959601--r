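#' Construct a PeakSet of sorted genomic intervals
#'
#' A `PeakSet` is the unit of all overlap work: a set of 0-based half-open
#' intervals `[start, end)` sorted by (chrom, start, end), each carrying an
#' optional summit (bp offset from `start`) and an optional score. Peaks are
#' unstranded.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0 <= start < end, half-open.
#' @param name optional interval names (defaults to `peak_1`, ...).
#' @param score optional numeric score.
#' @param summit optional bp offset from `start`, in `[0, end - start)`.
#'   Defaults to the interval midpoint, `floor((end - start) / 2)`.
#' @param set_name label for the whole set (factor/condition/replicate).
#' @param layout optional [genome_layout()]; when supplied, intervals must lie
#'   within their chromosome.
#' @return A `PeakSet`: a sorted data.frame with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `summit` and attribute `set_name`.
#' @examples
#' peak_set("chr1", 100, 200, summit = 25)
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NA_real_,
                     summit = NULL, set_name = "peaks", layout = NULL) {
  n <- length(start)
  if (n == 0L) {
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), name = character(0),
                     score = numeric(0), summit = numeric(0),
                     stringsAsFactors = FALSE)
    attr(df, "set_name") <- set_name
    class(df) <- c("PeakSet", "data.frame")
    return(df)
  }
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (is.null(name)) {
    name <- if (n) paste0("peak_", seq_len(n)) else character(0)
  }
  score <- rep_len(as.numeric(score), n)
  if (is.null(summit)) summit <- floor((end - start) / 2)
  summit <- as.numeric(summit)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = as.character(name), score = score, summit = summit,
                   stringsAsFactors = FALSE)
  validate_peak_set(df, layout = layout)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "set_name") <- set_name
  class(df) <- c("PeakSet", "data.frame")
  df
}

validate_peak_set <- function(df, layout = NULL) {
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("PeakSet: start/end must not be NA", call. = FALSE)
  }
  bad <- df$start < 0 | df$start >= df$end
  if (any(bad)) {
    stop("PeakSet: invalid interval(s) (need 0 <= start < end) at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  off <- df$summit
  badsum <- !is.na(off) & (off < 0 | off >= df$end - df$start)
  if (any(badsum)) {
    stop("PeakSet: summit offset outside [0, width) at row(s) ",
         paste(utils::head(which(badsum), 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(layout)) {
    len <- .layout_length(layout, df$chrom)
    out <- df$end > len
    if (any(out)) {
      stop("PeakSet: interval(s) extend beyond chromosome at row(s) ",
           paste(utils::head(which(out), 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d interval(s) on %d chromosome(s)\n",
              attr(x, "set_name") %||% "peaks", nrow(x),
              length(unique(x$chrom))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# absolute summit coordinate (0-based)
summit_pos <- function(ps) ps$start + ps$summit

# PeakSet -> GRanges (1-based closed, the Bioconductor convention)
ps_granges <- function(ps) {
  GenomicRanges::GRanges(
    seqnames = ps$chrom,
    ranges = IRanges::IRanges(start = ps$start + 1, end = ps$end)
  )
}

# GRanges -> PeakSet (back to 0-based half-open)
granges_ps <- function(gr, set_name = "peaks") {
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1,
           GenomicRanges::end(gr),
           set_name = set_name)
}

#' Subset a PeakSet, keeping its class and label
#'
#' @param x a PeakSet.
#' @param i row index.
#' @return A PeakSet.
#' @export
ps_subset <- function(x, i) {
  df <- as.data.frame(x)[i, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "set_name") <- attr(x, "set_name")
  class(df) <- c("PeakSet", "data.frame")
  df
}
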