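#' Binding matrix: loci x factors presence/absence with a region class
#'
#' Emulates a multi-factor ChIP compendium reduced to binary co-binding
#' calls: each locus carries a genomic class label and a 0/1 membership per
#' transcription factor.
#'
#' @param membership logical or 0/1 matrix, loci x factors (named columns).
#' @param class character vector of class labels per locus, drawn from
#'   `classes`.
#' @param loci optional [peak_set()] of locus coordinates.
#' @param classes allowed class labels.
#' @return A `BindingMatrix` (list with `membership`, `class`, `loci`).
#' @export
binding_matrix <- function(membership, class,
                           loci = NULL,
                           classes = c("DE_promoter", "enhancer",
                                       "super_enhancer", "other")) {
  membership <- as.matrix(membership) > 0
  if (is.null(colnames(membership)) || ncol(membership) < 1) {
    stop("binding_matrix: membership needs >= 1 named factor column", call. = FALSE)
  }
  class <- as.character(class)
  if (length(class) != nrow(membership)) {
    stop("binding_matrix: one class label per locus required", call. = FALSE)
  }
  if (!all(class %in% classes)) {
    stop("binding_matrix: unknown class label(s): ",
         paste(setdiff(unique(class), classes), collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(membership))) {
    rownames(membership) <- if (!is.null(loci)) loci$name else
      paste0("locus_", seq_len(nrow(membership)))
  }
  structure(list(membership = membership, class = class, loci = loci,
                 classes = classes),
            class = "BindingMatrix")
}

#' Pairwise phi correlation of factor binding vectors
#'
#' The phi coefficient (Pearson correlation of 0/1 vectors) for every pair
#' of factors. A factor bound everywhere or nowhere has no variance; its
#' correlations are undefined and recorded as `NA`.
#'
#' @param bm a [binding_matrix()].
#' @return Symmetric factor x factor matrix with unit diagonal (where
#'   defined).
#' @export
phi_correlation <- function(bm) {
  m <- bm$membership * 1
  if (nrow(m) < 2) stop("phi_correlation: need >= 2 loci", call. = FALSE)
  suppressWarnings(stats::cor(m))
}

#' Select cofactors of a target by phi correlation
#'
#' Factors whose phi with the target reaches `min_phi`, sorted by descending
#' phi then name, optionally truncated to the strongest `top_k`. Factors
#' with undefined phi (constant binding vectors) are excluded with a
#' warning.
#'
#' @param bm a [binding_matrix()].
#' @param target factor name present in the matrix.
#' @param min_phi phi threshold (default 0.2).
#' @param top_k optional cap on the number of cofactors returned.
#' @return Named numeric vector of phi values, ordered; names are the
#'   selected cofactors.
#' @export
select_cofactors <- function(bm, target, min_phi = 0.2, top_k = NULL) {
  if (!target %in% colnames(bm$membership)) {
    stop("select_cofactors: unknown target '", target, "'", call. = FALSE)
  }
  phi <- phi_correlation(bm)[target, ]
  phi <- phi[names(phi) != target]
  if (anyNA(phi)) {
    warning("select_cofactors: undefined phi for ",
            paste(names(phi)[is.na(phi)], collapse = ", "), " (excluded)")
    phi <- phi[!is.na(phi)]
  }
  phi <- phi[phi >= min_phi]
  phi <- phi[order(-phi, names(phi))]
  if (!is.null(top_k)) phi <- utils::head(phi, top_k)
  phi
}

#' Exact co-binding combination counts within a region class
#'
#' Each locus of the class contributes to exactly one combination: its
#' exact membership pattern over the chosen factors (UpSet "distinct" mode,
#' matching counts of instances of a specific factor set). Combinations are
#' ranked by count (descending), ties by lexicographic pattern; counts sum
#' to the number of loci in the class.
#'
#' @param bm a [binding_matrix()].
#' @param class one of the matrix's class labels, present in the data.
#' @param factors ordered factor names to tally over (default all).
#' @return data.frame `(combination, count)`; combination is a
#'   `+`-separated factor list, `"(none)"` for loci bound by no chosen
#'   factor.
#' @export
combination_counts_by_class <- function(bm, class, factors = NULL) {
  if (is.null(factors)) factors <- colnames(bm$membership)
  if (!all(factors %in% colnames(bm$membership))) {
    stop("combination_counts_by_class: unknown factor(s)", call. = FALSE)
  }
  sel <- bm$class == class
  if (!any(sel)) stop("combination_counts_by_class: empty class '", class, "'",
                      call. = FALSE)
  m <- bm$membership[sel, factors, drop = FALSE]
  pat <- apply(m, 1, function(r) {
    if (!any(r)) "(none)" else paste(factors[r], collapse = "+")
  })
  cnt <- table(pat)
  out <- data.frame(combination = names(cnt), count = as.numeric(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a BindingMatrix as TSV
#'
#' Layout: `locus_id, chrom, start, end, class`, then one 0/1 column per
#' factor.
#'
#' @param bm a [binding_matrix()].
#' @param path TSV path.
#' @export
write_binding_matrix <- function(bm, path) {
  loci <- bm$loci
  df <- data.frame(locus_id = rownames(bm$membership),
                   chrom = if (!is.null(loci)) loci$chrom else ".",
                   start = if (!is.null(loci)) format_coord(loci$start) else 0,
                   end = if (!is.null(loci)) format_coord(loci$end) else 0,
                   class = bm$class)
  df <- cbind(df, as.data.frame(bm$membership * 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_matrix
#' @export
read_binding_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("locus_id", "chrom", "start", "end", "class")
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(m) <- df$locus_id
  loci <- NULL
  if (!all(df$chrom == ".")) {
    loci <- peak_set(df$chrom, df$start, df$end, name = df$locus_id)
  }
  binding_matrix(m, class = df$class, loci = loci,
                 classes = unique(c(df$class, "other")))
}
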