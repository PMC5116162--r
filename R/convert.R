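# Format conversion between SGA and the neighboring standard formats.
# BED/GFF/narrowPeak parsing is delegated to rtracklayer; SGA and BED output
# lines are formatted here so round trips are byte-exact.

.NARROWPEAK_COLS <- c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer")

#' Convert BED intervals to SGA
#'
#' Three conversion modes are supported. \code{five_prime} maps each interval
#' to the 1-based coordinate of its 5' end: \code{start + 1} (strand
#' \code{+}) for plus-strand or strandless intervals, \code{end} (strand
#' \code{-}) for minus-strand intervals; one count per line, then compacted.
#' \code{narrowpeak_summit} maps each ENCODE narrowPeak line to its summit
#' (\code{start + 1 + offset}, column 10); an offset of -1 (no summit called)
#' falls back to the interval midpoint; strand \code{0}.
#' \code{region_pair} emits regions-SGA boundary pairs
#' (\code{start + 1}, \code{end}) carrying the BED score as count
#' (floored at 1).
#'
#' @param file path to a BED (or narrowPeak) file.
#' @param feature feature label to assign.
#' @param mode one of \code{"five_prime"}, \code{"narrowpeak_summit"},
#'   \code{"region_pair"}.
#' @return a sorted, compacted \code{sga} object (boundary-pair lines in
#'   \code{region_pair} mode; use \code{\link{sga_to_regions}} to get the
#'   interval form).
#' @export
bed_to_sga <- function(file, feature,
                       mode = c("five_prime", "narrowpeak_summit",
                                "region_pair")) {
  mode <- match.arg(mode)
  gr <- tryCatch({
    if (mode == "narrowpeak_summit")
      rtracklayer::import(file, format = "BED", extraCols = .NARROWPEAK_COLS)
    else
      rtracklayer::import(file, format = "BED")
  }, error = function(e) {
    if (mode == "narrowpeak_summit" && grepl("column|scan|extra", conditionMessage(e),
                                             ignore.case = TRUE))
      stop("narrowPeak input must have 10 columns: ", conditionMessage(e),
           call. = FALSE)
    stop("BED import failed (check 0-based start < end): ",
         conditionMessage(e), call. = FALSE)
  })
  if (length(gr) == 0L) return(sga(sorted = TRUE))
  if (any(IRanges::width(gr) < 1L))
    stop("BED interval with end <= start", call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start1 <- GenomicRanges::start(gr)   # rtracklayer: already 1-based
  end1 <- GenomicRanges::end(gr)
  std <- as.character(GenomicRanges::strand(gr))
  out <- switch(mode,
    five_prime = {
      minus <- std == "-"
      sga(chrom, feature,
          position = ifelse(minus, end1, start1),
          strand = ifelse(minus, "-", "+"),
          count = 1L)
    },
    narrowpeak_summit = {
      off <- gr$peak
      pos <- ifelse(off >= 0L, start1 + off,
                    (start1 + end1) %/% 2L)
      sga(chrom, feature, position = pos, strand = "0", count = 1L)
    },
    region_pair = {
      score <- if (!is.null(gr$score)) gr$score else rep(1, length(gr))
      score[is.na(score)] <- 1
      regions_to_sga(sga_regions(chrom, start1, end1,
                                 pmax(1L, as.integer(score)), feature))
    })
  if (mode == "region_pair") sort_records(out) else compact(sort_records(out))
}

#' Convert GFF features to SGA
#'
#' Each GFF feature is mapped to the 1-based coordinate of its 5' end
#' (start for \code{+} or strandless features, end for \code{-} features).
#' The GFF type column becomes the SGA feature label unless overridden.
#'
#' @param file path to a GFF file.
#' @param feature optional feature label overriding the GFF type column.
#' @return a sorted, compacted \code{sga} object.
#' @export
gff_to_sga <- function(file, feature = NULL) {
  gr <- rtracklayer::import(file, format = "gff")
  if (length(gr) == 0L) return(sga(sorted = TRUE))
  std <- as.character(GenomicRanges::strand(gr))
  minus <- std == "-"
  feat <- if (is.null(feature)) as.character(gr$type) else feature
  strand_out <- ifelse(std == "+", "+", ifelse(minus, "-", "0"))
  compact(sort_records(sga(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    feature = feat,
    position = ifelse(minus, GenomicRanges::end(gr),
                      GenomicRanges::start(gr)),
    strand = strand_out, count = 1L)))
}

#' Convert mapped reads (BAM/SAM) to SGA
#'
#' Each primary mapped alignment contributes one tag at the genomic position
#' of its 5' end: the leftmost reference base for forward alignments, the
#' rightmost aligned reference base (CIGAR-aware, spanning D and N
#' operations) for reverse alignments. Unmapped, secondary and supplementary
#' alignments are skipped, as are alignments below the mapping-quality
#' cutoff. The result is sorted and compacted so the count field gives the
#' number of reads sharing a 5' position.
#'
#' @param file path to a BAM file (a \code{.sam} text file is converted on
#'   the fly).
#' @param feature feature label to assign.
#' @param min_mapq minimum mapping quality (default 0).
#' @return a sorted, compacted \code{sga} object.
#' @export
bam_to_sga <- function(file, feature, min_mapq = 0L) {
  if (grepl("\\.sam$", file, ignore.case = TRUE))
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   mapqFilter = as.integer(min_mapq))
  aln <- GenomicAlignments::readGAlignments(file, param = param)
  if (length(aln) == 0L) return(sga(sorted = TRUE))
  std <- as.character(GenomicAlignments::strand(aln))
  minus <- std == "-"
  compact(sort_records(sga(
    chrom = as.character(GenomicAlignments::seqnames(aln)),
    feature = feature,
    position = ifelse(minus, GenomicAlignments::end(aln),
                      GenomicAlignments::start(aln)),
    strand = ifelse(minus, "-", "+"),
    count = 1L)))
}

#' Convert SGA to BED lines
#'
#' \code{single_base} writes one 6-column BED line per record
#' (\code{chrom, pos-1, pos, feature, count, strand}; strand \code{0}
#' becomes \code{.}). \code{region_pairs} interprets the stream as
#' alternating regions-SGA boundary lines and writes one interval
#' (\code{start-1, end}) per pair.
#'
#' @param x a sorted \code{sga} object.
#' @param mode \code{"single_base"} or \code{"region_pairs"}.
#' @param file optional path; when given the lines are also written there.
#' @return a character vector of BED lines.
#' @export
sga_to_bed <- function(x, mode = c("single_base", "region_pairs"),
                       file = NULL) {
  mode <- match.arg(mode)
  if (!is_sorted(x)) stop("sga_to_bed requires a sorted stream", call. = FALSE)
  lines <- if (mode == "single_base") {
    strand <- ifelse(x$strand == "0", ".", x$strand)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s",
            x$chrom, x$position - 1L, x$position, x$feature, x$count, strand)
  } else {
    reg <- sga_to_regions(x)
    sprintf("%s\t%d\t%d\t%s\t%d\t.",
            reg$chrom, reg$start - 1L, reg$end, reg$feature, reg$count)
  }
  if (!is.null(file)) writeLines(lines, file)
  lines
}
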