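#' Genome layout (chromosome names and lengths)
#'
#' A minimal description of the reference: one row per chromosome with its
#' length in base pairs. All interval validation is performed against a
#' layout, and every coordinate in the package is 0-based half-open.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths (bp), all positive.
#' @return A `GenomeLayout`: a data.frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(10000, 5000))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    stop("genome_layout: chromosome names must be unique", call. = FALSE)
  }
  if (any(is.na(length)) || any(length <= 0)) {
    stop("genome_layout: chromosome lengths must be positive", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("GenomeLayout", "data.frame")
  out
}

#' Read chromosome sizes from a 2-column TSV ("chrom<TAB>length")
#'
#' @param path file path.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom sizes file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "numeric"))
  genome_layout(x[[1]], x[[2]])
}

#' Write chromosome sizes as a 2-column TSV
#'
#' @param layout a [genome_layout()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.layout_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in layout: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  layout$length[i]
}
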