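#' Merge intervals within a gap
#'
#' Intervals closer than or equal to `gap` bp apart are merged; at `gap = 0`
#' this is the union of coverage, with bookended half-open intervals
#' (`[a,b)`, `[b,c)`) merging into `[a,c)`. Idempotent. Summits of merged
#' intervals are reset to midpoints.
#'
#' @param peaks a [peak_set()].
#' @param gap non-negative bp.
#' @return A [peak_set()] of disjoint intervals.
#' @export
merge_intervals <- function(peaks, gap = 0) {
  stopifnot(gap >= 0)
  if (!nrow(peaks)) return(peaks)
  gr <- GenomicRanges::reduce(ps_granges(peaks), min.gapwidth = gap + 1)
  granges_ps(gr, set_name = attr(peaks, "set_name") %||% "merged")
}

#' Consensus peaks: bases supported by at least k of n replicates
#'
#' Returns the maximal runs of base pairs covered by at least `min_support`
#' replicate peak sets (the strict reading of a "k of n replicates" consensus
#' rule, e.g. 3 of 4). Each replicate is flattened first so overlapping peaks
#' within one replicate count once. Adjacent qualifying runs are merged and
#' each output interval's summit is its midpoint.
#'
#' @param replicates list of [peak_set()], one per replicate.
#' @param min_support minimum number of supporting replicates (>= 1).
#' @param set_name label for the output set.
#' @return A [peak_set()] of consensus regions.
#' @examples
#' r1 <- peak_set("chr1", 100, 200)
#' r2 <- peak_set("chr1", 150, 250)
#' r3 <- peak_set("chr1", 180, 220)
#' consensus_peaks(list(r1, r2, r3), min_support = 2)
#' @export
consensus_peaks <- function(replicates, min_support, set_name = "consensus") {
  if (!is.list(replicates) || !length(replicates)) {
    stop("consensus_peaks: 'replicates' must be a non-empty list", call. = FALSE)
  }
  if (min_support < 1 || min_support > length(replicates)) {
    stop("consensus_peaks: min_support must be in [1, number of replicates]",
         call. = FALSE)
  }
  grl <- lapply(replicates, function(p) GenomicRanges::reduce(ps_granges(p)))
  nonempty <- grl[vapply(grl, length, 1L) > 0]
  if (!length(nonempty)) {
    return(peak_set(character(0), numeric(0), numeric(0), set_name = set_name))
  }
  covs <- lapply(nonempty, GenomicRanges::coverage)
  chroms <- sort(unique(unlist(lapply(covs, names))))
  res <- lapply(chroms, function(ch) {
    per <- lapply(covs, function(cv) {
      if (ch %in% names(cv)) cv[[ch]] else S4Vectors::Rle(0L, 0)
    })
    maxlen <- max(vapply(per, length, 1L))
    tot <- Reduce(`+`, lapply(per, function(r) {
      if (length(r) < maxlen) c(r, S4Vectors::Rle(0L, maxlen - length(r))) else r
    }))
    ir <- IRanges::slice(tot, lower = min_support, rangesOnly = TRUE)
    if (!length(ir)) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) {
    return(peak_set(character(0), numeric(0), numeric(0), set_name = set_name))
  }
  peak_set(res$chrom, res$start, res$end,
           name = paste0("consensus_", seq_len(nrow(res))), set_name = set_name)
}

#' Overlap membership matrix: which tracks touch each query interval
#'
#' @param query a [peak_set()].
#' @param tracks named list of [peak_set()].
#' @return Logical matrix (query interval x track); `TRUE` iff the query
#'   interval overlaps >= 1 bp of any interval in that track.
#' @export
overlap_membership <- function(query, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- paste0("track_", seq_along(tracks))
  }
  qgr <- ps_granges(query)
  m <- vapply(tracks, function(tr) {
    if (!nrow(tr)) return(rep(FALSE, nrow(query)))
    suppressWarnings(GenomicRanges::countOverlaps(qgr, ps_granges(tr))) > 0
  }, logical(nrow(query)))
  m <- matrix(m, nrow = nrow(query), dimnames = list(query$name, names(tracks)))
  m
}

#' Signed distance from peak summits to the nearest TSS
#'
#' For each peak the nearest TSS by `|summit - position|` is reported with a
#' strand-aware sign: positive means the summit lies downstream of the TSS in
#' the gene's orientation. Ties go to the lexicographically smallest
#' `gene_id`. Peaks on chromosomes without any TSS get `NA` (with a warning);
#' an entirely empty TSS table is an error.
#'
#' @param peaks a [peak_set()].
#' @param tss a [tss_table()].
#' @return data.frame with columns `name`, `gene_id`, `distance`.
#' @export
tss_distance <- function(peaks, tss) {
  if (!nrow(tss)) stop("tss_distance: empty TSS table", call. = FALSE)
  s <- summit_pos(peaks)
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (!length(ti)) next
    o <- order(tss$position[ti], tss$gene_id[ti])
    pos <- tss$position[ti][o]
    gid <- tss$gene_id[ti][o]
    str <- tss$strand[ti][o]
    # smallest gene_id per duplicated position (sorted by (pos, gene) above)
    first <- !duplicated(pos)
    upos <- pos[first]; ugid <- gid[first]; ustr <- str[first]
    k <- findInterval(s[pi], upos)
    left <- pmax(k, 1L)
    right <- pmin(k + 1L, length(upos))
    dl <- abs(s[pi] - upos[left])
    dr <- abs(s[pi] - upos[right])
    dl[k < 1L] <- Inf
    dr[k + 1L > length(upos)] <- Inf
    use_right <- dr < dl | (dr == dl & ugid[right] < ugid[left])
    best <- ifelse(use_right, right, left)
    bd <- ifelse(use_right, dr, dl)
    raw <- s[pi] - upos[best]
    dist[pi] <- ifelse(ustr[best] == "+", raw, -raw)
    gene[pi] <- ugid[best]
  }
  if (anyNA(gene)) {
    warning("tss_distance: no TSS on chromosome(s) of ", sum(is.na(gene)),
            " peak(s); distance set to NA")
  }
  data.frame(name = peaks$name, gene_id = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Classify a signed TSS distance into promoter bins or distal
#'
#' Default bins follow the common promoter-annotation convention:
#' `|d| <= 1 kb`, 1-2 kb, 2-3 kb, and distal beyond the last break.
#'
#' @param distance signed bp distance(s), as from [tss_distance()].
#' @param breaks increasing positive bp breaks (default `c(1000, 2000, 3000)`).
#' @return character vector of region-class labels.
#' @export
classify_region <- function(distance, breaks = c(1000, 2000, 3000)) {
  stopifnot(length(breaks) >= 1, all(diff(breaks) > 0))
  labs <- c(paste0("promoter_<=", breaks[1] / 1000, "kb"),
            if (length(breaks) > 1) {
              paste0("promoter_", breaks[-length(breaks)] / 1000, "-",
                     breaks[-1] / 1000, "kb")
            })
  ad <- abs(distance)
  idx <- findInterval(ad, breaks, left.open = TRUE) + 1
  out <- ifelse(idx > length(breaks), "distal", labs[pmin(idx, length(labs))])
  out[is.na(distance)] <- NA_character_
  out
}
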