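#' Region x sample read-count matrix with sample metadata
#'
#' Container for the count evidence behind differential-binding calls: one
#' row per consensus region, one column per ChIP sample, with each sample
#' assigned to a condition ("induced" or "vehicle") and a replicate id.
#'
#' @param counts integer matrix, regions x samples, all counts >= 0.
#' @param regions a [peak_set()] with `nrow(counts)` rows giving the region
#'   coordinates, or `NULL` for coordinate-free matrices.
#' @param condition character vector, one of "induced"/"vehicle" per sample.
#' @param replicate replicate ids (defaults to 1..n within condition).
#' @return A `CountMatrix` (list with `counts`, `regions`, `samples`).
#' @export
count_matrix <- function(counts, regions = NULL, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("count_matrix: counts must be non-negative", call. = FALSE)
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("count_matrix: one condition per sample required", call. = FALSE)
  }
  if (!all(condition %in% c("induced", "vehicle"))) {
    stop("count_matrix: condition must be 'induced' or 'vehicle'", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- if (!is.null(regions)) regions$name else
      paste0("region_", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("count_matrix: region ids must be unique", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(condition, "_", replicate)
  }
  if (!is.null(regions) && nrow(regions) != nrow(counts)) {
    stop("count_matrix: regions/counts dimension mismatch", call. = FALSE)
  }
  out <- list(counts = counts, regions = regions,
              samples = data.frame(sample = colnames(counts),
                                   condition = condition,
                                   replicate = as.character(replicate),
                                   stringsAsFactors = FALSE))
  class(out) <- "CountMatrix"
  out
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d regions x %d samples (%d induced, %d vehicle)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "induced"),
              sum(x$samples$condition == "vehicle")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median ratio of each sample's
#' counts to the per-region geometric mean, over regions with all-nonzero
#' counts (the standard library-size normalization for count matrices).
#'
#' @param x a [count_matrix()] or a plain counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "CountMatrix")) x$counts else as.matrix(x)
  if (any(colSums(m) == 0)) {
    stop("size_factors: a sample has no nonzero counts", call. = FALSE)
  }
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("size_factors: no region with all-nonzero counts", call. = FALSE)
  }
  sf <- apply(m, 2, function(cnt) exp(stats::median(log(cnt[use]) - loggeo[use])))
  names(sf) <- colnames(m)
  sf
}

#' Moderated-t test for differential binding per region
#'
#' The statistic works on `y = log2(count / size_factor + 0.5)`. Per region,
#' `log2FC = mean(y_induced) - mean(y_vehicle)`; the pooled within-condition
#' variance is shrunk toward the across-region mean variance with prior
#' weight `d0` (an empirical-Bayes-style stabilizer for few replicates), and
#' the two-sided p-value is taken from a t distribution with
#' `n1 + n2 - 2 + d0` degrees of freedom.
#'
#' @param x a [count_matrix()] with >= 2 replicates per condition.
#' @param d0 prior weight on the common variance (default 4).
#' @param pseudo pseudo-count added before log2 (default 0.5).
#' @param sf optional precomputed size factors (default [size_factors()]).
#' @return data.frame (`DiffBindRecord`s): `region_id`, `log2FC`, `t`, `p`,
#'   plus region coordinates when present in `x`.
#' @export
test_region_differential <- function(x, d0 = 4, pseudo = 0.5, sf = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  ind <- x$samples$condition == "induced"
  veh <- x$samples$condition == "vehicle"
  n1 <- sum(ind); n2 <- sum(veh)
  if (n1 < 2 || n2 < 2) {
    stop("test_region_differential: need >= 2 replicates per condition",
         call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(x)
  y <- log2(sweep(x$counts, 2, sf, "/") + pseudo)
  m1 <- rowMeans(y[, ind, drop = FALSE])
  m2 <- rowMeans(y[, veh, drop = FALSE])
  lfc <- m1 - m2
  v1 <- rowSums((y[, ind, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((y[, veh, drop = FALSE] - m2)^2) / (n2 - 1)
  df_res <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_res
  s2_mod <- (d0 * mean(s2) + df_res * s2) / (d0 + df_res)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = df_res + d0)
  out <- data.frame(region_id = rownames(x$counts), log2FC = lfc, t = tstat,
                    p = p, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(x$regions)) {
    out <- cbind(out, x$regions[, c("chrom", "start", "end", "summit")])
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone and order-preserving.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Classify regions as gained / lost / unchanged at an FDR threshold
#'
#' A region is gained iff `q < alpha` and `log2FC > 0`, lost iff `q < alpha`
#' and `log2FC < 0`, unchanged otherwise.
#'
#' @param records output of [test_region_differential()]; a `q` column is
#'   added via [bh_adjust()] if absent.
#' @param alpha FDR threshold (default 0.05).
#' @return List with `records` (plus `q` and `direction` columns), and
#'   `gained` / `lost` [peak_set()]s when coordinates are available.
#' @export
classify_sites <- function(records, alpha = 0.05) {
  if (is.null(records$q)) records$q <- bh_adjust(records$p)
  records$direction <- ifelse(records$q < alpha & records$log2FC > 0, "gained",
                       ifelse(records$q < alpha & records$log2FC < 0, "lost",
                              "unchanged"))
  out <- list(records = records)
  if (all(c("chrom", "start", "end") %in% names(records))) {
    mk <- function(dir) {
      r <- records[records$direction == dir, , drop = FALSE]
      peak_set(r$chrom, r$start, r$end, name = r$region_id,
               summit = r$summit, set_name = dir)
    }
    out$gained <- mk("gained")
    out$lost <- mk("lost")
  }
  out
}

#' Write / read a CountMatrix as TSV
#'
#' Layout: columns `region_id, chrom, start, end`, then one column per
#' sample; the sample sheet (`sample, condition, replicate`) travels as a
#' separate TSV.
#'
#' @param x a [count_matrix()].
#' @param path counts TSV path.
#' @param samples_path sample sheet TSV path.
#' @export
write_count_matrix <- function(x, path, samples_path) {
  reg <- x$regions
  df <- data.frame(region_id = rownames(x$counts),
                   chrom = if (!is.null(reg)) reg$chrom else ".",
                   start = if (!is.null(reg)) format_coord(reg$start) else 0,
                   end = if (!is.null(reg)) format_coord(reg$end) else 0)
  df <- cbind(df, as.data.frame(x$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, samples_path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ss <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cnt <- as.matrix(df[, ss$sample, drop = FALSE])
  rownames(cnt) <- df$region_id
  regions <- NULL
  if (!all(df$chrom == ".")) {
    regions <- peak_set(df$chrom, df$start, df$end, name = df$region_id)
    # peak_set sorts by coordinate; keep counts aligned with the regions
    cnt <- cnt[match(regions$name, rownames(cnt)), , drop = FALSE]
  }
  count_matrix(cnt, regions = regions, condition = ss$condition,
               replicate = ss$replicate)
}
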