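# Preprocessing: tag centering (shifting) and blacklist-region filtering.

#' Center (shift) ChIP-seq tags
#'
#' Shifts plus-strand tags downstream and minus-strand tags upstream by a
#' fixed distance -- typically half the immunoprecipitated fragment length --
#' so that tags from both strands pile up on the protein binding site.
#' Unoriented (\code{0}) records are left in place. All output strands are
#' set to \code{0}; records shifted below position 1 are dropped; coincident
#' positions are merged with summed counts; extra fields are dropped.
#'
#' @param x a sorted \code{sga} object.
#' @param distance non-negative shift in bp (e.g. 75 for ~150 bp fragments).
#' @return a sorted, compacted, unoriented \code{sga} object.
#' @export
center_tags <- function(x, distance) {
  if (!is_sorted(x)) stop("center_tags requires a sorted stream", call. = FALSE)
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 0L)
    stop("centering distance must be a non-negative integer", call. = FALSE)
  pos <- x$position +
    ifelse(x$strand == "+", distance, ifelse(x$strand == "-", -distance, 0L))
  keep <- pos >= 1L
  out <- sga(chrom = x$chrom[keep], feature = x$feature[keep],
             position = pos[keep], strand = "0", count = x$count[keep])
  compact(sort_records(out))
}

#' Filter SGA records by genomic regions
#'
#' Removes (or with \code{invert}, keeps only) records whose position falls
#' inside any of the given regions; both region boundaries are inclusive.
#' Typical use: eliminating tags or peaks inside blacklisted repeat regions.
#' Extra fields and record order are preserved; the default and inverted
#' calls partition the input exactly.
#'
#' @param x a sorted \code{sga} object (the data feature).
#' @param regions an \code{sga_regions} object, or a boundary-pair
#'   \code{sga} stream (regions SGA).
#' @param invert if \code{TRUE}, keep only records inside the regions.
#' @return a sorted \code{sga} object.
#' @export
filter_by_regions <- function(x, regions, invert = FALSE) {
  if (!is_sorted(x))
    stop("filter_by_regions requires a sorted stream", call. = FALSE)
  if (inherits(regions, "sga")) regions <- sga_to_regions(regions)
  if (!inherits(regions, "sga_regions"))
    stop("regions must be an sga_regions object or a regions-SGA stream",
         call. = FALSE)
  if (nrow(x) == 0L || nrow(regions) == 0L) {
    keep <- rep(!invert, nrow(x))
    return(.new_sga(as.data.frame(x)[keep, , drop = FALSE], sorted = TRUE))
  }
  inside <- logical(nrow(x))
  for (chr in unique(regions$chrom)) {
    sel <- which(x$chrom == chr)
    if (length(sel) == 0L) next
    r <- regions[regions$chrom == chr, ]
    idx <- findInterval(x$position[sel], r$start)
    hit <- idx > 0L
    hit[hit] <- x$position[sel][hit] <= r$end[idx[hit]]
    inside[sel] <- hit
  }
  keep <- if (invert) inside else !inside
  .new_sga(as.data.frame(x)[keep, , drop = FALSE], sorted = TRUE)
}
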