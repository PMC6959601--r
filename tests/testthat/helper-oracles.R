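# Independent brute-force oracles. Each deliberately re-derives its result
# from first principles (per-base sweeps, all-pairs scans, enumeration) and
# never calls the implementation path it checks.

# consensus: per-base support-depth sweep over an explicit base grid
oracle_consensus <- function(replicates, min_support, genome_len = 10000,
                             chroms = NULL) {
  if (is.null(chroms)) {
    chroms <- sort(unique(unlist(lapply(replicates, function(p) p$chrom))))
  }
  out <- NULL
  for (ch in chroms) {
    depth <- integer(genome_len)
    for (rep in replicates) {
      covered <- logical(genome_len)
      ri <- rep[rep$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(ri))) {
        covered[(ri$start[k] + 1):ri$end[k]] <- TRUE  # 1-based base b-1..b
      }
      depth <- depth + covered
    }
    ok <- depth >= min_support
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    out <- rbind(out, data.frame(chrom = ch, start = starts[keep] - 1,
                                 end = ends[keep]))
  }
  out
}

# overlap membership: naive all-pairs scan
oracle_membership <- function(query, tracks) {
  m <- matrix(FALSE, nrow(query), length(tracks))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    for (i in seq_len(nrow(query))) {
      m[i, j] <- any(tr$chrom == query$chrom[i] &
                       tr$start < query$end[i] & tr$end > query$start[i])
    }
  }
  m
}

# nearest TSS: exhaustive search with smallest-gene-id tie break
oracle_nearest_tss <- function(peaks, tss) {
  s <- peaks$start + peaks$summit
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(data.frame(gene_id = NA, distance = NA))
    d <- abs(s[i] - cand$position)
    best <- which(d == min(d))
    best <- best[order(cand$gene_id[best])][1]
    raw <- s[i] - cand$position[best]
    data.frame(gene_id = cand$gene_id[best],
               distance = if (cand$strand[best] == "+") raw else -raw)
  })
  do.call(rbind, res)
}

# BH step-up from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    prev <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- prev
  }
  q
}

# Fisher two-sided p by exhaustive hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher_p <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  pobs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# enrichment score: literal single-pass running sum; near-ties in the two
# extremes (below float noise) resolve positive, as documented
oracle_es <- function(ranked, members, weight = 1) {
  hit <- names(ranked) %in% members
  N <- length(ranked); m <- sum(hit)
  w <- abs(as.numeric(ranked))^weight
  denom <- sum(w[hit])
  run <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / m
    } else -1 / (N - m)
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (abs(hi) - abs(lo) >= -1e-12) hi else lo
}

# combination tally: dictionary over pattern strings
oracle_combo_tally <- function(membership, factors) {
  pats <- apply(membership[, factors, drop = FALSE], 1, function(r) {
    if (!any(r)) "(none)" else paste(factors[as.logical(r)], collapse = "+")
  })
  tab <- table(pats)
  df <- data.frame(combination = names(tab), count = as.numeric(tab))
  df[order(-df$count, df$combination), ]
}

# naive both-strand PWM scan over every offset
oracle_scan <- function(sequence, pw) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(sequence), "")[[1]]
  w <- ncol(pw$mat)
  m <- pmax(pw$mat, 1e-4)
  m <- sweep(m, 2, colSums(m), "/")
  lo <- log2(m / pw$background)
  score_word <- function(word) {
    s <- 0
    for (j in seq_len(w)) {
      b <- word[j]
      s <- s + if (b %in% rownames(lo)) unname(lo[b, j]) else 0
    }
    s
  }
  best <- list(score = -Inf, offset = NA, strand = NA)
  for (off in 0:(length(chars) - w)) {
    win <- chars[(off + 1):(off + w)]
    for (strand in c("+", "-")) {
      word <- if (strand == "+") win else rev(unname(comp[win]))
      word[is.na(word)] <- "N"
      sc <- score_word(word)
      if (sc > best$score + 1e-12) {
        best <- list(score = sc, offset = off, strand = strand)
      }
    }
  }
  best
}

random_peakset <- function(n, chroms = c("chr1", "chr2"), max_pos = 9000,
                           max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  peak_set(chrom, start, start + width)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_pwm <- function(w = 8) {
  m <- matrix(stats::rgamma(4 * w, 1), 4)
  m <- sweep(m, 2, colSums(m), "/")
  pwm(m, name = "rand")
}
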