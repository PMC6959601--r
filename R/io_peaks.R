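#' Read an ENCODE narrowPeak (or BED-like) file into a PeakSet
#'
#' Accepts 6 to 10 tab-separated columns. With 10 columns the 10th is the
#' summit offset from `start`; an offset of -1 (peak callers use this for "no
#' point source") or a file with fewer than 10 columns yields the interval
#' midpoint, `floor(width / 2)`. Column 7 (signalValue), when present, is
#' kept as the peak score; otherwise column 5 is used.
#'
#' @param path file path.
#' @param layout optional [genome_layout()] used to validate intervals.
#' @param set_name label for the resulting set (defaults to the file name).
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path, layout = NULL, set_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(set_name)) set_name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  if (!length(fields)) {
    return(peak_set(character(0), numeric(0), numeric(0), set_name = set_name))
  }
  nf <- lengths(fields)
  if (any(nf < 6 | nf > 10)) {
    bad <- lineno[which(nf < 6 | nf > 10)[1]]
    stop(sprintf("%s: line %d has %d fields (expected 6-10)", path, bad,
                 nf[which(nf < 6 | nf > 10)[1]]), call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("%s: line %d: non-numeric start/end", path, bad), call. = FALSE)
  }
  badiv <- start < 0 | start >= end
  if (any(badiv)) {
    stop(sprintf("%s: line %d: invalid interval (need 0 <= start < end)",
                 path, lineno[which(badiv)[1]]), call. = FALSE)
  }
  name <- get(4)
  score5 <- suppressWarnings(as.numeric(get(5)))
  signal <- suppressWarnings(as.numeric(get(7)))
  score <- ifelse(is.na(signal), score5, signal)
  peak10 <- suppressWarnings(as.numeric(get(10)))
  width <- end - start
  summit <- ifelse(!is.na(peak10) & peak10 >= 0, peak10, floor(width / 2))
  badsum <- summit < 0 | summit >= width
  if (any(badsum)) {
    stop(sprintf("%s: line %d: summit offset outside interval", path,
                 lineno[which(badsum)[1]]), call. = FALSE)
  }
  peak_set(chrom, start, end, name = name, score = score, summit = summit,
           set_name = set_name, layout = layout)
}

#' Read a BED file (3-6 columns) into a PeakSet
#'
#' @inheritParams read_narrowpeak
#' @return A [peak_set()]; summits default to midpoints.
#' @export
read_bed <- function(path, layout = NULL, set_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(set_name)) set_name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (!any(keep)) {
    return(peak_set(character(0), numeric(0), numeric(0), set_name = set_name))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("%s: line %d has fewer than 3 fields", path,
                 lineno[which(nf < 3)[1]]), call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("%s: line %d: non-numeric start/end", path,
                 lineno[which(is.na(start) | is.na(end))[1]]), call. = FALSE)
  }
  name <- get(4)
  name[is.na(name)] <- paste0("feat_", which(is.na(name)))
  score <- suppressWarnings(as.numeric(get(5)))
  peak_set(get(1), start, end, name = name, score = score,
           set_name = set_name, layout = layout)
}

#' Write a PeakSet as BED6
#'
#' Coordinates are written 0-based half-open in (chrom, start, end) order;
#' strand is "." (peaks are unstranded) and missing scores become 0. The
#' summit is not representable in BED6 (use [write_narrowpeak()] to keep it);
#' a set with midpoint summits round-trips exactly through [read_bed()].
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  if (!nrow(peaks)) {
    ok <- tryCatch({ writeLines(character(0), path); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) stop("write_bed: cannot write ", path, call. = FALSE)
    return(invisible(path))
  }
  df <- data.frame(peaks$chrom, format_coord(peaks$start),
                   format_coord(peaks$end), peaks$name,
                   ifelse(is.na(peaks$score), 0, peaks$score), ".")
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_bed: cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write a PeakSet as 10-column narrowPeak (keeps summits)
#'
#' @inheritParams write_bed
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, format_coord(peaks$start),
                   format_coord(peaks$end), peaks$name, 0, ".",
                   ifelse(is.na(peaks$score), 0, peaks$score), -1, -1,
                   format_coord(peaks$summit))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# integer-style formatting for coordinates stored as doubles
format_coord <- function(x) formatC(x, format = "d")

#' Read a stranded TSS table from BED6
#'
#' Rows are `chrom, position, position+1, gene_id, score, strand`; the TSS
#' position is 0-based.
#'
#' @param path file path.
#' @param layout optional [genome_layout()].
#' @return A `TssTable` data.frame with columns `gene_id`, `chrom`,
#'   `position`, `strand`.
#' @export
read_tss <- function(path, layout = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "character", "character"))
  tss_table(gene_id = x[[4]], chrom = x[[1]], position = x[[2]],
            strand = x[[6]], layout = layout)
}

#' Construct a TSS table
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param position 0-based TSS coordinates.
#' @param strand "+" or "-" (gene orientation).
#' @param layout optional [genome_layout()].
#' @return A `TssTable` data.frame.
#' @export
tss_table <- function(gene_id, chrom, position, strand, layout = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("tss_table: gene_id must be unique", call. = FALSE)
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) {
    stop("tss_table: strand must be '+' or '-'", call. = FALSE)
  }
  position <- as.numeric(position)
  if (!is.null(layout)) {
    len <- .layout_length(layout, as.character(chrom))
    if (any(position >= len)) stop("tss_table: position beyond chromosome", call. = FALSE)
  }
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    position = position, strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("TssTable", "data.frame")
  out
}

#' Write a TSS table as BED6
#'
#' @param tss a [tss_table()].
#' @param path output path.
#' @export
write_tss <- function(tss, path) {
  df <- data.frame(tss$chrom, format_coord(tss$position),
                   format_coord(tss$position + 1), tss$gene_id, 0, tss$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
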