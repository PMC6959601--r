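#' Paired primary/metastasis expression container
#'
#' Count matrix of genes x samples where samples come in matched
#' primary/metastasis pairs (one pair per patient).
#'
#' @param counts gene x sample matrix of non-negative counts; rownames are
#'   gene ids.
#' @param pair patient/pair id per sample.
#' @param tissue "primary" or "metastasis" per sample.
#' @return A `PairedCounts` list.
#' @export
paired_counts <- function(counts, pair, tissue) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("paired_counts: negative counts", call. = FALSE)
  tissue <- as.character(tissue)
  if (!all(tissue %in% c("primary", "metastasis"))) {
    stop("paired_counts: tissue must be 'primary' or 'metastasis'", call. = FALSE)
  }
  pair <- as.character(pair)
  tab <- table(pair, tissue)
  if (!all(tab == 1)) {
    stop("paired_counts: each pair needs exactly one primary and one metastasis",
         call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  }
  structure(list(counts = counts,
                 samples = data.frame(sample = colnames(counts) %||%
                                        paste0(pair, "_", tissue),
                                      pair = pair, tissue = tissue,
                                      stringsAsFactors = FALSE)),
            class = "PairedCounts")
}

#' Ranked list from matched primary/metastasis pairs
#'
#' Counts are library-size normalized by median-of-ratios and moved to
#' `y = log2(norm + 0.5)`; per gene and pair the metastasis-minus-primary
#' difference `d` is formed. In `"replicates"` mode all pairs act as
#' replicates: the score is the mean difference scaled by a
#' pooled-dispersion standard error (the per-gene across-pair variance of
#' `d`, moderated toward the across-gene mean variance with prior weight
#' `d0`). In `"single_pair"` mode one pair is scored alone,
#' `d_target / sqrt(s2)`, with its dispersion `s2` estimated from the
#' remaining pairs (moderated the same way) - the paired design in which a
#' single patient is judged against the spread of the rest.
#'
#' @param pc a [paired_counts()] with >= 2 pairs.
#' @param mode `"replicates"` or `"single_pair"`.
#' @param target_pair pair id, required in single-pair mode.
#' @param d0 prior weight for variance moderation (default 4).
#' @return A [ranked_list()] over all genes, descending score.
#' @export
paired_ranking <- function(pc, mode = c("replicates", "single_pair"),
                           target_pair = NULL, d0 = 4) {
  mode <- match.arg(mode)
  pairs <- unique(pc$samples$pair)
  if (length(pairs) < 2) stop("paired_ranking: need >= 2 pairs", call. = FALSE)
  sf <- size_factors(pc$counts)
  y <- log2(sweep(pc$counts, 2, sf, "/") + 0.5)
  d <- vapply(pairs, function(pr) {
    mi <- which(pc$samples$pair == pr & pc$samples$tissue == "metastasis")
    pi <- which(pc$samples$pair == pr & pc$samples$tissue == "primary")
    y[, mi] - y[, pi]
  }, numeric(nrow(y)))
  colnames(d) <- pairs
  moderated_var <- function(mat) {
    k <- ncol(mat)
    mu <- rowMeans(mat)
    s2 <- rowSums((mat - mu)^2) / (k - 1)
    (d0 * mean(s2) + (k - 1) * s2) / (d0 + k - 1)
  }
  if (mode == "replicates") {
    s2 <- moderated_var(d)
    mu <- rowMeans(d)
    score <- ifelse(s2 > 0, mu / sqrt(s2 / length(pairs)),
                    ifelse(mu == 0, 0, sign(mu) * Inf))
  } else {
    if (is.null(target_pair) || !target_pair %in% pairs) {
      stop("paired_ranking: target_pair absent", call. = FALSE)
    }
    rest <- d[, setdiff(pairs, target_pair), drop = FALSE]
    if (ncol(rest) < 2) stop("paired_ranking: need >= 2 other pairs", call. = FALSE)
    s2 <- moderated_var(rest)
    dt <- d[, target_pair]
    score <- ifelse(s2 > 0, dt / sqrt(s2),
                    ifelse(dt == 0, 0, sign(dt) * Inf))
  }
  ranked_list(rownames(pc$counts), score)
}

#' Bidirectional patient-pair enrichment screen
#'
#' For every pair, builds the single-pair ranked list and tests a signature
#' gene set with [permutation_test()], then BH-adjusts across pairs - the
#' per-patient design asking which metastases are enriched for a
#' binding-derived expression signature.
#'
#' @param pc a [paired_counts()].
#' @param signature a [gene_set()].
#' @param n_perm permutations per pair (default 1e4).
#' @param seed master seed; each pair uses a derived stream.
#' @param weight ES weight exponent.
#' @return data.frame, one row per pair: `pair, es, nes, p_perm, padj`.
#' @export
patient_pair_enrichment <- function(pc, signature, n_perm = 1e4, seed = 1,
                                    weight = 1) {
  pairs <- unique(pc$samples$pair)
  rows <- lapply(seq_along(pairs), function(i) {
    rk <- paired_ranking(pc, mode = "single_pair", target_pair = pairs[i])
    r <- permutation_test(rk, signature, weight = weight, n_perm = n_perm,
                          seed = seed + i)
    data.frame(pair = pairs[i], es = r$es, nes = r$nes, p_perm = r$p_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_perm)
  out
}

#' Write / read paired counts as TSV (genes x samples, with a sample sheet)
#'
#' @param pc a [paired_counts()].
#' @param path counts TSV path.
#' @param samples_path sample sheet TSV path.
#' @export
write_paired_counts <- function(pc, path, samples_path) {
  df <- cbind(data.frame(gene = rownames(pc$counts)), as.data.frame(pc$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pc$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_paired_counts
#' @export
read_paired_counts <- function(path, samples_path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ss <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cnt <- as.matrix(df[, ss$sample, drop = FALSE])
  rownames(cnt) <- df$gene
  paired_counts(cnt, pair = ss$pair, tissue = ss$tissue)
}
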