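# Sliding-window peak calling restricted to tag-hit positions, with a
# vicinity-range local-maximum rule and optional weighted-average refinement.

# Sparse-table range maximum over vals[lo..hi], vectorized over queries.
.range_max <- function(vals, lo, hi) {
  n <- length(vals)
  K <- max(0L, floor(log2(n)))
  st <- vector("list", K + 1L)
  st[[1L]] <- vals
  len <- 1L
  for (k in seq_len(K)) {
    prev <- st[[k]]
    m <- length(prev) - len
    st[[k + 1L]] <- pmax(prev[seq_len(m)], prev[seq_len(m) + len])
    len <- len * 2L
  }
  span <- hi - lo + 1L
  k <- pmin(floor(log2(span)), K)
  res <- numeric(length(lo))
  for (kk in unique(k)) {
    i <- which(k == kk)
    p2 <- 2L^kk
    # maximum over [lo, lo+p2-1] and [hi-p2+1, hi]
    res[i] <- pmax(st[[kk + 1L]][lo[i]], st[[kk + 1L]][hi[i] - p2 + 1L])
  }
  res
}

.call_peaks_one <- function(pos, cnt, width, threshold, vicinity, refine) {
  n <- length(pos)
  if (n == 0L)
    return(data.frame(position = integer(), count = integer()))
  r <- width %/% 2L
  P <- .make_prefix(pos, cnt)
  wc <- P(pos + r) - P(pos - r - 1L)
  # dominance key: higher window count wins; ties go to the leftmost
  # candidate, encoded as a fractional bonus decreasing with position
  key <- wc + (max(pos) - pos) / (max(pos) + 1)
  lo <- findInterval(pos - vicinity - 0.5, pos) + 1L
  hi <- findInterval(pos + vicinity, pos)
  win <- .range_max(key, lo, hi)
  sel <- wc >= threshold & key >= win
  out_pos <- pos[sel]
  if (refine && any(sel)) {
    PW <- .make_prefix(pos, pos * as.numeric(cnt))
    wsum <- PW(pos[sel] + r) - PW(pos[sel] - r - 1L)
    out_pos <- as.integer(floor(wsum / wc[sel] + 0.5))
  }
  data.frame(position = as.integer(out_pos), count = as.integer(wc[sel]))
}

#' Call peaks in an SGA tag stream
#'
#' Sliding-window peak finder: candidate positions are the distinct tag
#' positions; the window count of a candidate p is the total tag count
#' within \code{floor(width/2)} bp of p (a centered window of effective
#' width \code{2*floor(width/2) + 1}). A candidate is reported as a peak if
#' its window count reaches the tag threshold and no other candidate within
#' the vicinity range has a greater window count (ties are broken in favor
#' of the leftmost candidate). With \code{refine}, the reported position is
#' the count-weighted average tag position within the window (rounded, half
#' up); refinement relocates peaks but does not change which candidates are
#' selected. No control sample is used.
#'
#' @param x a sorted \code{sga} object (single feature).
#' @param width window width in bp.
#' @param threshold minimum number of tags in the window.
#' @param vicinity vicinity range in bp within which a peak must be a local
#'   maximum.
#' @param refine report the weighted-average position instead of the
#'   candidate position.
#' @param oriented call peaks separately per strand instead of pooling
#'   strands.
#' @param count_ceiling optional cap on the count at any single position,
#'   applied per input record before pooling.
#' @param feature feature label for the output records (default
#'   \code{"PEAK"}).
#' @return a sorted \code{sga} object with one record per peak; the count
#'   field holds the window tag count; strand is \code{0} unless
#'   \code{oriented}.
#' @export
call_peaks <- function(x, width, threshold, vicinity, refine = FALSE,
                       oriented = FALSE, count_ceiling = NULL,
                       feature = "PEAK") {
  if (width < 1L || threshold < 1L || vicinity < 1L)
    stop("width, threshold and vicinity must all be >= 1", call. = FALSE)
  if (!is_sorted(x)) stop("call_peaks requires a sorted stream", call. = FALSE)
  df <- as.data.frame(x)
  if (!is.null(count_ceiling)) df$count <- pmin(df$count, as.integer(count_ceiling))
  groups <- if (oriented) split(df, list(df$chrom, df$strand), drop = TRUE)
            else split(df, df$chrom)
  res <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    agg <- rowsum(as.numeric(d$count), d$position)
    pos <- as.integer(rownames(agg))
    o <- order(pos)
    pk <- .call_peaks_one(pos[o], as.integer(agg[o, 1L]),
                          width, threshold, vicinity, refine)
    if (nrow(pk) == 0L) return(NULL)
    data.frame(chrom = d$chrom[1L], feature = feature,
               position = pk$position,
               strand = if (oriented) d$strand[1L] else "0",
               count = pk$count, extras = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(sga(sorted = TRUE))
  out <- sort_records(.new_sga(res, sorted = FALSE))
  attr(out, "params") <- list(width = width, threshold = threshold,
                              vicinity = vicinity, refine = refine,
                              oriented = oriented)
  out
}

#' Tag threshold from a fold change over the average count density
#'
#' Expresses the peak caller's tag threshold as a fold change over the
#' sample's genome-wide average count density, which behaves reproducibly
#' across data sets of different depth: with background density
#' \code{lambda = total_count / genome_length}, the threshold is the
#' expected window content at \code{fold} times background,
#' \code{ceiling(fold * lambda * (2*floor(width/2) + 1))}, floored at 1.
#'
#' @param fold fold change over the average count density (> 0).
#' @param width peak window width in bp.
#' @param total_count total tag count of the sample.
#' @param genome_length total genome length in bp.
#' @return an integer tag threshold.
#' @export
threshold_from_fold <- function(fold, width, total_count, genome_length) {
  if (fold <= 0) stop("fold must be positive", call. = FALSE)
  stopifnot(total_count >= 1, genome_length >= 1)
  lambda <- total_count / genome_length
  eff <- 2L * (width %/% 2L) + 1L
  max(1L, as.integer(ceiling(fold * lambda * eff)))
}
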