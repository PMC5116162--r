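# Genome segmentation into signal-enriched regions by a linear-time
# dynamic program over tag positions, maximizing a global score in which
# each enriched segment [a, k] contributes
#   (sum of counts in [a, k]) - rho * (x_k - x_a + 1) - penalty.

.segment_one <- function(pos, cnt, rho, penalty) {
  n <- length(pos)
  best <- numeric(n + 1L)           # best[k+1] = optimum over first k positions
  M <- -Inf                         # running max of best[a-1] - P[a-1] + rho*x_a
  amax <- 0L
  choice <- integer(n)              # 0 = no segment ends at k, else start index a
  P <- cumsum(as.numeric(cnt))
  P0 <- c(0, P)
  for (k in seq_len(n)) {
    cand_a <- best[k] - P0[k] + rho * pos[k]
    if (cand_a > M) { M <- cand_a; amax <- k }
    seg <- P[k] - rho * pos[k] - rho - penalty + M
    if (seg > best[k]) {            # ties favor "no segment ends at k"
      best[k + 1L] <- seg
      choice[k] <- amax
    } else {
      best[k + 1L] <- best[k]
      choice[k] <- 0L
    }
  }
  starts <- integer(0); ends <- integer(0)
  k <- n
  while (k >= 1L) {
    if (choice[k] == 0L) { k <- k - 1L } else {
      a <- choice[k]
      starts <- c(a, starts); ends <- c(k, ends)
      k <- a - 1L
    }
  }
  list(start = pos[starts], end = pos[ends],
       count = as.integer(P0[ends + 1L] - P0[starts]),
       score = best[n + 1L])
}

#' Partition a genome into signal-enriched segments
#'
#' Dynamic-programming segmenter ("broad peak" finder) for histone-mark-like
#' data: each chromosome is partitioned into an alternating series of
#' enriched and depleted regions by maximizing a global score in which an
#' enriched segment spanning tag positions \code{[a, k]} contributes its
#' total count minus \code{rho} per spanned bp minus a per-segment
#' transition penalty. \code{rho} (counts per bp) sets the enriched/depleted
#' border; a higher penalty merges fragments into larger regions. Optimal
#' segments always start and end exactly at tag positions. Strands are
#' pooled before segmentation.
#'
#' @param x a sorted \code{sga} object.
#' @param rho count density threshold in counts per bp (> 0); see
#'   \code{\link{rho_from_fold}}.
#' @param penalty transition penalty charged once per enriched segment
#'   (>= 0).
#' @param count_ceiling optional cap on the count of any single input
#'   record.
#' @param feature feature label for the output regions (default
#'   \code{"PART"}).
#' @return an \code{sga_regions} object (serialize with
#'   \code{\link{regions_to_sga}}); the total score is attached as attribute
#'   \code{"score"}.
#' @export
segment_genome <- function(x, rho, penalty, count_ceiling = NULL,
                           feature = "PART") {
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  if (penalty < 0) stop("penalty must be non-negative", call. = FALSE)
  if (!is_sorted(x)) stop("segment_genome requires a sorted stream", call. = FALSE)
  df <- as.data.frame(x)
  if (!is.null(count_ceiling)) df$count <- pmin(df$count, as.integer(count_ceiling))
  chroms <- unique(df$chrom)
  parts <- lapply(chroms, function(chr) {
    d <- df[df$chrom == chr, ]
    agg <- rowsum(as.numeric(d$count), d$position)   # pool strands
    pos <- as.integer(rownames(agg))
    o <- order(pos)
    .segment_one(pos[o], as.integer(agg[o, 1L]), rho, penalty)
  })
  out <- sga_regions(
    chrom = rep(chroms, vapply(parts, function(p) length(p$start), 1L)),
    start = unlist(lapply(parts, `[[`, "start")),
    end = unlist(lapply(parts, `[[`, "end")),
    count = unlist(lapply(parts, `[[`, "count")),
    feature = feature)
  attr(out, "score") <- sum(vapply(parts, `[[`, numeric(1), "score"))
  attr(out, "params") <- list(rho = rho, penalty = penalty)
  out
}

#' Score a segmentation against a tag stream
#'
#' Independent re-scorer: recounts, for each region, the total tag count
#' (strands pooled) from the stream and returns the global segmentation
#' score \code{sum(C - rho * length - penalty)}. Pure function of its
#' inputs; accepts any disjoint region set, not only optimizer output.
#'
#' @param regions an \code{sga_regions} object.
#' @param x a sorted \code{sga} object.
#' @param rho,penalty segmentation parameters (see
#'   \code{\link{segment_genome}}).
#' @return the numeric global score (0 for an empty segmentation).
#' @export
segmentation_score <- function(regions, x, rho, penalty) {
  if (nrow(regions) == 0L) return(0)
  score <- 0
  for (i in seq_len(nrow(regions))) {
    sel <- x$chrom == regions$chrom[i] &
      x$position >= regions$start[i] & x$position <= regions$end[i]
    C <- sum(as.numeric(x$count[sel]))
    L <- regions$end[i] - regions$start[i] + 1
    score <- score + C - rho * L - penalty
  }
  score
}

#' Count density threshold from a fold change
#'
#' Expresses the segmentation density threshold \code{rho} as a fold change
#' over the sample's genome-wide average count density, giving reproducible
#' behavior across data sets of different sequencing depth.
#'
#' @param fold fold change (> 0).
#' @param total_count total tag count of the sample.
#' @param genome_length total genome length in bp.
#' @return \code{rho} in counts per bp.
#' @export
rho_from_fold <- function(fold, total_count, genome_length) {
  if (fold <= 0) stop("fold must be positive", call. = FALSE)
  stopifnot(total_count >= 1, genome_length >= 1)
  fold * total_count / genome_length
}
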