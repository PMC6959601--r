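#' Ranked gene list
#'
#' Genes ordered by a real-valued score, descending; among equal scores the
#' order is ascending gene id, making every downstream statistic
#' deterministic.
#'
#' @param genes unique gene ids.
#' @param scores numeric scores (one per gene).
#' @return A `RankedList`: named numeric vector, sorted.
#' @export
ranked_list <- function(genes, scores) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("ranked_list: duplicate gene ids", call. = FALSE)
  if (length(genes) != length(scores)) {
    stop("ranked_list: genes/scores length mismatch", call. = FALSE)
  }
  o <- order(-scores, genes)
  out <- stats::setNames(as.numeric(scores)[o], genes[o])
  class(out) <- c("RankedList", "numeric")
  out
}

#' Gene set
#'
#' @param members unique gene ids.
#' @param name set name.
#' @return A `GeneSet` list.
#' @export
gene_set <- function(members, name = "set") {
  members <- unique(as.character(members))
  structure(list(name = name, members = members), class = "GeneSet")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom; a set member ("hit") at rank i
#' increments the running sum by `|s_i|^weight / sum_hits |s|^weight`, a
#' non-member decrements it by `1/(N - |S|)`. The enrichment score is the
#' running sum's extreme deviation from zero (maximum by absolute value,
#' sign kept; an exact tie between the positive and negative extreme
#' resolves to the positive one). `weight = 0` recovers the classic
#' unweighted KS statistic. If every hit has score 0 the hit increments
#' fall back to equal weights `1/|S|`.
#'
#' @param ranked a [ranked_list()].
#' @param set a [gene_set()] (or character vector); must intersect the list
#'   and must not equal it.
#' @param weight score exponent (default 1).
#' @param return_curve also return the running-sum curve (for plotting).
#' @return List `es` and, if requested, `curve` (length N running sum).
#' @export
enrichment_score <- function(ranked, set, weight = 1, return_curve = FALSE) {
  members <- if (inherits(set, "GeneSet")) set$members else as.character(set)
  N <- length(ranked)
  hit <- names(ranked) %in% members
  m <- sum(hit)
  if (m == 0) stop("enrichment_score: set does not intersect the ranked list",
                   call. = FALSE)
  if (m == N) stop("enrichment_score: set equals the entire ranked list",
                   call. = FALSE)
  w <- abs(as.numeric(ranked))^weight
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / m, N)
  step <- ifelse(hit, inc, -1 / (N - m))
  curve <- cumsum(step)
  hi <- max(curve)
  lo <- min(curve)
  # ties in |extreme| below numerical noise resolve to the positive side
  es <- if (abs(hi) - abs(lo) >= -1e-12) hi else lo
  if (return_curve) list(es = es, curve = curve) else list(es = es)
}

# ES from sorted hit positions without touching the other N-m entries;
# absw = |score|^weight aligned with the full ranked list
es_from_positions <- function(pos, absw, N) {
  m <- length(pos)
  wts <- absw[pos]
  denom <- sum(wts)
  cumhit <- if (denom > 0) cumsum(wts) / denom else seq_len(m) / m
  miss <- 1 / (N - m)
  # value at each hit, and just before each hit (local extremes of the walk)
  top <- cumhit - (pos - seq_len(m)) * miss
  bot <- c(0, cumhit[-m]) - (pos - seq_len(m)) * miss
  hi <- max(top)
  lo <- min(bot)
  if (abs(hi) - abs(lo) >= -1e-12) hi else lo
}

#' Gene-set permutation test for rank enrichment
#'
#' The null draws `n_perm` random gene sets of size `|S|` from the ranked
#' list without replacement. The permutation p-value uses the add-one
#' estimator over same-sign null scores,
#' `p = (1 + #\{same-sign |ES_null| >= |ES|\}) / (1 + #same-sign)`, and the
#' normalized score is `NES = ES / mean(|ES_null| same sign)`. Deterministic
#' given `seed`. Fewer than 10 same-sign permutations raises an
#' unstable-null warning.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100; default 1e5, the scale
#'   typically used for published enrichment p-values).
#' @param seed integer seed for the permutation stream.
#' @return An `EnrichmentResult` list: `set`, `es`, `nes`, `p_perm`,
#'   `n_perm`, `n_same_sign`, `leading_edge`, `trailing_edge`, `size`.
#' @export
permutation_test <- function(ranked, set, weight = 1, n_perm = 1e5, seed = 1) {
  if (n_perm < 100) stop("permutation_test: n_perm must be >= 100", call. = FALSE)
  members <- if (inherits(set, "GeneSet")) set$members else as.character(set)
  set_name <- if (inherits(set, "GeneSet")) set$name else "set"
  obs <- enrichment_score(ranked, members, weight = weight, return_curve = TRUE)
  N <- length(ranked)
  hitpos <- which(names(ranked) %in% members)
  m <- length(hitpos)
  absw <- abs(as.numeric(ranked))^weight
  null_es <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort(sample.int(N, m)), absw, N)
    }, numeric(1))
  })
  same <- sign(null_es) == sign(obs$es)
  n_same <- sum(same)
  if (n_same < 10) {
    warning("permutation_test: fewer than 10 same-sign permutations; ",
            "null is unstable")
  }
  p <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + n_same)
  nes <- if (n_same > 0) obs$es / mean(abs(null_es[same])) else NA_real_
  curve <- obs$curve
  hitnames <- names(ranked)[hitpos]
  if (obs$es >= 0) {
    peak <- which.max(curve)
    leading <- hitnames[hitpos <= peak]
    trough <- which.min(curve)
    trailing <- hitnames[hitpos > trough]
  } else {
    trough <- which.min(curve)
    leading <- hitnames[hitpos >= trough]
    peak <- which.max(curve)
    trailing <- hitnames[hitpos <= peak]
  }
  structure(list(set = set_name, es = obs$es, nes = nes, p_perm = p,
                 n_perm = n_perm, n_same_sign = n_same,
                 leading_edge = leading, trailing_edge = trailing, size = m),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult '%s': ES %.3f, NES %.3f, p %.4g (%d perms, size %d)\n",
              x$set, x$es, x$nes, x$p_perm, x$n_perm, x$size))
  invisible(x)
}

# run code with a local RNG state seeded by `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Batch rank-enrichment over several gene sets with BH adjustment
#'
#' @param ranked a [ranked_list()].
#' @param sets list of [gene_set()]s.
#' @inheritParams permutation_test
#' @return data.frame with one row per set (`set, size, es, nes, p_perm,
#'   padj, leading_edge`), `padj` from [bh_adjust()] over the batch.
#' @export
enrichment_batch <- function(ranked, sets, weight = 1, n_perm = 1e5, seed = 1) {
  res <- lapply(seq_along(sets), function(i) {
    permutation_test(ranked, sets[[i]], weight = weight, n_perm = n_perm,
                     seed = seed + i)
  })
  df <- do.call(rbind, lapply(res, function(r) {
    data.frame(set = r$set, size = r$size, es = r$es, nes = r$nes,
               p_perm = r$p_perm,
               leading_edge = paste(r$leading_edge, collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  df$padj <- bh_adjust(df$p_perm)
  df[, c("set", "size", "es", "nes", "p_perm", "padj", "leading_edge")]
}

#' Gene set of genes with a peak summit near their TSS
#'
#' A gene joins the set iff any peak summit lies within `max_distance` bp of
#' its TSS (the 10 kb ChIP-to-gene assignment rule).
#'
#' @param peaks a [peak_set()].
#' @param tss a [tss_table()].
#' @param max_distance bp (default 10000).
#' @param name set name.
#' @return A [gene_set()] (possibly empty).
#' @export
chip_gene_set <- function(peaks, tss, max_distance = 10000, name = "chip") {
  if (!nrow(peaks)) return(gene_set(character(0), name = name))
  s <- summit_pos(peaks)
  keep <- vapply(seq_len(nrow(tss)), function(i) {
    any(peaks$chrom == tss$chrom[i] & abs(s - tss$position[i]) <= max_distance)
  }, logical(1))
  gene_set(tss$gene_id[keep], name = name)
}

#' Ranked list from a differential-expression table
#'
#' Score is `sign(log2FC) * (-log10 p)`: monotone in both direction and
#' evidence. Descending order, ties by ascending gene id.
#'
#' @param de data.frame with columns `gene`, `log2FC`, `p` (p in (0, 1]).
#' @return A [ranked_list()].
#' @export
de_ranked_list <- function(de) {
  if (anyDuplicated(de$gene)) stop("de_ranked_list: duplicate genes", call. = FALSE)
  if (any(de$p <= 0 | de$p > 1)) {
    stop("de_ranked_list: p must lie in (0, 1]", call. = FALSE)
  }
  ranked_list(de$gene, sign(de$log2FC) * (-log10(de$p)))
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT path.
#' @return List of [gene_set()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gene_set(f[-(1:2)], name = f[1])
  })
}

#' @rdname read_gmt
#' @param sets a [gene_set()] or list of them.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked list as 2-column RNK-style TSV
#'
#' @param ranked a [ranked_list()].
#' @param path output path.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(data.frame(gene = names(ranked), score = as.numeric(ranked)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
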