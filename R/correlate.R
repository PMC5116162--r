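# Feature correlation: aggregation profiles, per-reference count matrices
# and reference scoring/selection, computed from a merged two-feature SGA
# stream via per-chromosome prefix sums over target positions.

.select_feature <- function(x, feature, strand = "any", what = "feature") {
  sel <- x$feature == feature
  if (!any(sel))
    stop("feature '", feature, "' not present in the stream", call. = FALSE)
  if (strand != "any") sel <- sel & x$strand == strand
  x[sel, , drop = FALSE]
}

# Prefix-sum evaluator: total target count at positions <= q, vectorized
# over q. pos must be sorted ascending, cnt parallel.
.make_prefix <- function(pos, cnt) {
  cum <- c(0, cumsum(as.numeric(cnt)))
  function(q) cum[findInterval(q, pos) + 1L]
}

# Counts of targets per bin around each reference, as an n_ref x nbins
# matrix. Bin j (1-based) covers offsets [b + (j-1)w, b + jw) where the
# offset is t - r, negated for flipped (oriented minus-strand) references.
.bin_counts <- function(ref_pos, flipped, tgt_pos, tgt_cnt, b, e, w) {
  nbins <- (e - b) %/% w
  P <- .make_prefix(tgt_pos, tgt_cnt)
  out <- matrix(0, length(ref_pos), nbins)
  fwd <- !flipped
  if (any(fwd)) {
    # bin j: t in [r + b + (j-1)w, r + b + jw - 1]
    edges <- b + w * (0:nbins) - 1L
    m <- P(outer(ref_pos[fwd], edges, `+`))
    dim(m) <- c(sum(fwd), nbins + 1L)
    out[fwd, ] <- m[, -1L, drop = FALSE] - m[, -(nbins + 1L), drop = FALSE]
  }
  if (any(flipped)) {
    # offset d = r - t in [b + (j-1)w, b + jw - 1]
    # => t in [r - b - jw + 1, r - b - (j-1)w]
    edges <- -b - w * (0:nbins)
    m <- P(outer(ref_pos[flipped], edges, `+`))
    dim(m) <- c(sum(flipped), nbins + 1L)
    out[flipped, ] <- m[, -(nbins + 1L), drop = FALSE] - m[, -1L, drop = FALSE]
  }
  out
}

.check_cor_params <- function(b, e, w) {
  if (!(b < e)) stop("range begin must be < range end", call. = FALSE)
  if (w < 1L) stop("bin width must be >= 1", call. = FALSE)
  if ((e - b) %% w != 0L)
    stop("range width (end - begin) must be divisible by the bin width",
         call. = FALSE)
}

.genome_length <- function(x, genome) {
  if (!is.null(genome)) return(sum(as.numeric(genome)))
  warning("no chromosome-sizes table given; estimating genome length as the ",
          "sum of per-chromosome maximum observed positions", call. = FALSE)
  sum(vapply(split(x$position, x$chrom), function(p) as.numeric(max(p)),
             numeric(1)))
}

#' Aggregation profile of a target feature around reference positions
#'
#' Computes the binned abundance of a target feature at offsets in
#' \code{[b, e)} around each reference position (the classical aggregation /
#' metagene plot, and -- with plus-strand tags as reference and minus-strand
#' tags as target -- the 5'-3' strand cross-correlation plot whose maximum
#' estimates the mean fragment length). A reference record with count k
#' counts as k references. In \code{oriented} mode offsets are negated for
#' minus-strand references (reverse-complementary processing).
#'
#' Normalization modes: \code{count} (raw summed counts per bin),
#' \code{density} (counts per bp per reference: count / (w * n_ref)) and
#' \code{ratio} (density divided by the genome-wide average target density,
#' i.e. fold enrichment).
#'
#' @param x a sorted \code{sga} object holding both features (e.g. from
#'   \code{\link{sort_merge}}).
#' @param ref_feature,target_feature feature labels of the reference and
#'   target sets.
#' @param b,e offset range in bp relative to the reference (half-open
#'   \code{[b, e)}), \code{b < e}.
#' @param w bin width in bp; \code{(e - b)} must be divisible by \code{w}.
#' @param ref_strand,target_strand optional strand filters
#'   (\code{"+"}, \code{"-"} or \code{"any"}).
#' @param oriented process targets reverse-complementarily for minus-strand
#'   references.
#' @param normalization \code{"count"}, \code{"density"} or \code{"ratio"}.
#' @param genome named vector of chromosome lengths (needed for
#'   \code{ratio}; estimated from the data with a warning when absent).
#' @return an object of class \code{correlation_profile}: a list with
#'   \code{offset} (bin left edges), \code{value}, \code{n_ref},
#'   \code{total_target}, \code{normalization} and \code{params}.
#' @export
correlate_profile <- function(x, ref_feature, target_feature, b, e, w,
                              ref_strand = "any", target_strand = "any",
                              oriented = FALSE,
                              normalization = c("count", "density", "ratio"),
                              genome = NULL) {
  normalization <- match.arg(normalization)
  .check_cor_params(b, e, w)
  refs <- .select_feature(x, ref_feature, ref_strand)
  tgts <- .select_feature(x, target_feature, target_strand)
  nbins <- (e - b) %/% w
  bins <- numeric(nbins)
  for (chr in unique(refs$chrom)) {
    r <- refs[refs$chrom == chr, ]
    t <- tgts[tgts$chrom == chr, ]
    if (nrow(t) == 0L) next
    tp <- t$position; tc <- t$count
    o <- order(tp); tp <- tp[o]; tc <- tc[o]
    flipped <- oriented & (r$strand == "-")
    m <- .bin_counts(r$position, flipped, tp, tc, b, e, w)
    bins <- bins + colSums(m * r$count)
  }
  n_ref <- sum(as.numeric(refs$count))
  total_target <- sum(as.numeric(tgts$count))
  value <- switch(normalization,
    count = bins,
    density = bins / (w * n_ref),
    ratio = {
      gl <- .genome_length(x, genome)
      (bins / (w * n_ref)) / (total_target / gl)
    })
  structure(list(offset = b + w * (0:(nbins - 1L)), value = value,
                 n_ref = n_ref, total_target = total_target,
                 normalization = normalization,
                 params = list(b = b, e = e, w = w, oriented = oriented,
                               ref_feature = ref_feature,
                               target_feature = target_feature)),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("Correlation profile: ", x$params$ref_feature, " vs ",
      x$params$target_feature, ", ", length(x$value), " bins of ",
      x$params$w, " bp in [", x$params$b, ", ", x$params$e, "), ",
      x$normalization, " normalization, n_ref = ", x$n_ref, "\n", sep = "")
  invisible(x)
}

#' @method as.data.frame correlation_profile
#' @export
as.data.frame.correlation_profile <- function(x, ...) {
  data.frame(offset = x$offset, value = x$value)
}

#' Per-reference binned target count matrix
#'
#' Like \code{\link{correlate_profile}} (count mode) but resolved per
#' reference record: one row per reference line, one column per bin, cell
#' values the target counts in that bin around that reference (weighted by
#' the reference's count so that column sums equal the count-mode profile).
#' Suitable for heat-map display.
#'
#' @inheritParams correlate_profile
#' @return an integer matrix with row names \code{"chrom:pos:strand"} and
#'   bin left-edge offsets as an \code{"offsets"} attribute.
#' @export
extract_matrix <- function(x, ref_feature, target_feature, b, e, w,
                           ref_strand = "any", target_strand = "any",
                           oriented = FALSE) {
  .check_cor_params(b, e, w)
  refs <- .select_feature(x, ref_feature, ref_strand)
  tgts <- .select_feature(x, target_feature, target_strand)
  nbins <- (e - b) %/% w
  out <- matrix(0, nrow(refs), nbins)
  for (chr in unique(refs$chrom)) {
    ri <- which(refs$chrom == chr)
    t <- tgts[tgts$chrom == chr, ]
    if (nrow(t) == 0L) next
    tp <- t$position; tc <- t$count
    o <- order(tp); tp <- tp[o]; tc <- tc[o]
    flipped <- oriented & (refs$strand[ri] == "-")
    out[ri, ] <- .bin_counts(refs$position[ri], flipped, tp, tc, b, e, w) *
      refs$count[ri]
  }
  storage.mode(out) <- "integer"
  rownames(out) <- paste(refs$chrom, refs$position, refs$strand, sep = ":")
  attr(out, "offsets") <- b + w * (0:(nbins - 1L))
  out
}

#' Score references by nearby target counts
#'
#' Counts target features within a single window \code{[b, e)} around each
#' reference position (no binning) and appends the total as an extra field
#' to the reference line, preserving any existing extra fields -- so a
#' reference set can be annotated with tag counts from several experiments
#' in succession. With a threshold, acts as a feature selector: only
#' references whose window count reaches the threshold are kept.
#'
#' @inheritParams correlate_profile
#' @param threshold optional integer; references with window count below it
#'   are dropped (\code{threshold = 0} keeps all).
#' @return a sorted \code{sga} object of reference records with the window
#'   count appended to \code{extras}.
#' @export
score_references <- function(x, ref_feature, target_feature, b, e,
                             threshold = NULL, ref_strand = "any",
                             target_strand = "any", oriented = FALSE) {
  if (!(b < e)) stop("range begin must be < range end", call. = FALSE)
  refs <- .select_feature(x, ref_feature, ref_strand)
  tgts <- .select_feature(x, target_feature, target_strand)
  score <- numeric(nrow(refs))
  for (chr in unique(refs$chrom)) {
    ri <- which(refs$chrom == chr)
    t <- tgts[tgts$chrom == chr, ]
    if (nrow(t) == 0L) next
    tp <- t$position; tc <- t$count
    o <- order(tp); tp <- tp[o]; tc <- tc[o]
    P <- .make_prefix(tp, tc)
    rp <- refs$position[ri]
    flipped <- oriented & (refs$strand[ri] == "-")
    lo <- ifelse(flipped, rp - e + 1L, rp + b)
    hi <- ifelse(flipped, rp - b, rp + e - 1L)
    score[ri] <- P(hi) - P(lo - 1L)
  }
  df <- as.data.frame(refs)
  has <- nzchar(df$extras)
  df$extras[has] <- paste(df$extras[has], score[has], sep = "\t")
  df$extras[!has] <- as.character(score[!has])
  if (!is.null(threshold)) df <- df[score >= threshold, , drop = FALSE]
  sort_records(.new_sga(df, sorted = FALSE))
}
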