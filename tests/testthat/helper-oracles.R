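# Independent brute-force oracles. These deliberately use naive per-pair /
# per-position loops, unrelated to the prefix-sum sweeps in the package.

oracle_profile <- function(x, ref_feature, target_feature, b, e, w,
                           ref_strand = "any", target_strand = "any",
                           oriented = FALSE) {
  refs <- x[x$feature == ref_feature &
              (ref_strand == "any" | x$strand == ref_strand), ]
  tgts <- x[x$feature == target_feature &
              (target_strand == "any" | x$strand == target_strand), ]
  nb <- (e - b) %/% w
  bins <- numeric(nb)
  for (i in seq_len(nrow(refs))) {
    for (j in seq_len(nrow(tgts))) {
      if (refs$chrom[i] != tgts$chrom[j]) next
      d <- tgts$position[j] - refs$position[i]
      if (oriented && refs$strand[i] == "-") d <- -d
      if (d >= b && d < e) {
        k <- (d - b) %/% w + 1L
        bins[k] <- bins[k] + tgts$count[j] * refs$count[i]
      }
    }
  }
  bins
}

oracle_matrix <- function(x, ref_feature, target_feature, b, e, w,
                          ref_strand = "any", target_strand = "any",
                          oriented = FALSE) {
  refs <- x[x$feature == ref_feature &
              (ref_strand == "any" | x$strand == ref_strand), ]
  tgts <- x[x$feature == target_feature &
              (target_strand == "any" | x$strand == target_strand), ]
  nb <- (e - b) %/% w
  m <- matrix(0L, nrow(refs), nb)
  for (i in seq_len(nrow(refs))) {
    for (j in seq_len(nrow(tgts))) {
      if (refs$chrom[i] != tgts$chrom[j]) next
      d <- tgts$position[j] - refs$position[i]
      if (oriented && refs$strand[i] == "-") d <- -d
      if (d >= b && d < e) {
        k <- (d - b) %/% w + 1L
        m[i, k] <- m[i, k] + tgts$count[j] * refs$count[i]
      }
    }
  }
  m
}

oracle_score <- function(x, ref_feature, target_feature, b, e,
                         ref_strand = "any", target_strand = "any",
                         oriented = FALSE) {
  refs <- x[x$feature == ref_feature &
              (ref_strand == "any" | x$strand == ref_strand), ]
  tgts <- x[x$feature == target_feature &
              (target_strand == "any" | x$strand == target_strand), ]
  out <- numeric(nrow(refs))
  for (i in seq_len(nrow(refs))) {
    for (j in seq_len(nrow(tgts))) {
      if (refs$chrom[i] != tgts$chrom[j]) next
      d <- tgts$position[j] - refs$position[i]
      if (oriented && refs$strand[i] == "-") d <- -d
      if (d >= b && d < e) out[i] <- out[i] + tgts$count[j]
    }
  }
  out
}

oracle_filter_keep <- function(x, regions, invert = FALSE) {
  inside <- vapply(seq_len(nrow(x)), function(i) {
    any(regions$chrom == x$chrom[i] &
          regions$start <= x$position[i] & x$position[i] <= regions$end)
  }, logical(1))
  if (invert) inside else !inside
}

# Exhaustive peak scan: pools strands, recomputes window counts per
# candidate by direct summation and applies the local-max rule by a
# pairwise loop.
oracle_peaks <- function(x, width, threshold, vicinity) {
  out <- NULL
  for (chr in unique(x$chrom)) {
    d <- x[x$chrom == chr, ]
    agg <- tapply(d$count, d$position, sum)
    pos <- as.integer(names(agg))
    o <- order(pos); pos <- pos[o]; cnt <- as.integer(agg[o])
    r <- width %/% 2L
    wc <- vapply(pos, function(p) sum(cnt[abs(pos - p) <= r]), numeric(1))
    keep <- logical(length(pos))
    for (i in seq_along(pos)) {
      if (wc[i] < threshold) next
      ok <- TRUE
      for (j in seq_along(pos)) {
        if (i == j || abs(pos[j] - pos[i]) > vicinity) next
        if (wc[j] > wc[i] || (wc[j] == wc[i] && pos[j] < pos[i])) {
          ok <- FALSE; break
        }
      }
      keep[i] <- ok
    }
    if (any(keep))
      out <- rbind(out, data.frame(chrom = chr, position = pos[keep],
                                   count = as.integer(wc[keep])))
  }
  if (is.null(out)) data.frame(chrom = character(), position = integer(),
                               count = integer())
  else out[order(out$chrom, out$position), , drop = FALSE]
}

# Exhaustive enumeration of all sets of disjoint segments over tag
# positions; returns the maximum achievable segmentation score.
oracle_best_segmentation <- function(pos, cnt, rho, penalty) {
  n <- length(pos)
  if (n == 0L) return(0)
  cum <- c(0, cumsum(cnt))
  best <- 0
  rec <- function(i, acc) {
    if (acc > best) best <<- acc
    if (i > n) return(invisible())
    rec(i + 1L, acc)                       # no segment starts at i
    for (k in i:n) {                       # segment [i, k]
      sc <- (cum[k + 1L] - cum[i]) - rho * (pos[k] - pos[i] + 1) - penalty
      rec(k + 1L, acc + sc)
    }
  }
  rec(1L, 0)
  best
}

# Poisson upper-tail threshold by direct pmf summation.
oracle_poisson_threshold <- function(lambda, alpha) {
  t <- 0L
  repeat {
    upper <- 1 - sum(stats::dpois(0:(t - 1L), lambda))
    if (t > 0L && upper < alpha) return(max(2L, t))
    t <- t + 1L
  }
}
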