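#' @keywords internal
"_PACKAGE"

# Strand collation order: '+' < '-' < '0' (byte order of sorted text files).
.STRANDS <- c("+", "-", "0")

.strand_rank <- function(strand) match(strand, .STRANDS)

#' Construct an SGA stream
#'
#' An SGA (Simple Genome Annotation) stream is a data frame with one row per
#' genomic single-base annotation: chromosome, feature label, 1-based
#' position, strand (\code{"+"}, \code{"-"} or \code{"0"} for unoriented) and
#' a positive integer count. Extra fields beyond the five obligatory ones are
#' carried in a single tab-joined \code{extras} column (empty string when
#' absent). A logical \code{sorted} attribute records whether the records are
#' known to be ordered by (chromosome, position, strand).
#'
#' @param chrom character vector of sequence identifiers.
#' @param feature character vector of feature labels (non-empty, no tabs).
#' @param position integer vector of 1-based positions (>= 1).
#' @param strand character vector; each element one of \code{"+"},
#'   \code{"-"}, \code{"0"}.
#' @param count integer vector of read/feature counts (>= 1).
#' @param extras character vector of tab-joined additional fields
#'   (\code{""} for none).
#' @param sorted logical; if \code{NA} (default) sortedness is detected.
#' @return An object of class \code{sga} (a data frame).
#' @examples
#' sga(chrom = "chr1", feature = "CTCF", position = 1000L,
#'     strand = "+", count = 3L)
#' @export
sga <- function(chrom = character(), feature = character(),
                position = integer(), strand = character(),
                count = integer(), extras = character(), sorted = NA) {
  n <- length(position)
  if (length(extras) == 0L && n > 0L) extras <- rep("", n)
  x <- data.frame(chrom = as.character(chrom),
                  feature = as.character(feature),
                  position = as.integer(position),
                  strand = as.character(strand),
                  count = as.integer(count),
                  extras = as.character(extras),
                  stringsAsFactors = FALSE)
  x <- structure(x, class = c("sga", "data.frame"))
  validate_sga(x)
  attr(x, "sorted") <- if (is.na(sorted)) .check_sorted(x) else isTRUE(sorted)
  x
}

.new_sga <- function(df, sorted) {
  rownames(df) <- NULL
  structure(df[c("chrom", "feature", "position", "strand", "count", "extras")],
            class = c("sga", "data.frame"), sorted = isTRUE(sorted))
}

#' Validate SGA invariants
#'
#' Checks positions >= 1, counts >= 1, strands in \code{+,-,0}, non-empty
#' feature labels and absence of embedded tabs. Called by constructors;
#' useful after manual manipulation.
#'
#' @param x an \code{sga} object.
#' @return \code{x}, invisibly. Throws an error on violation.
#' @export
validate_sga <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$position) || any(x$position < 1L))
    stop("SGA positions must be integers >= 1", call. = FALSE)
  if (anyNA(x$count) || any(x$count < 1L))
    stop("SGA counts must be integers >= 1", call. = FALSE)
  bad <- !(x$strand %in% .STRANDS)
  if (any(bad))
    stop("invalid strand value(s): ",
         paste(unique(x$strand[bad]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(x$feature)))
    stop("feature names must be non-empty", call. = FALSE)
  if (any(grepl("\t", x$chrom, fixed = TRUE)) ||
      any(grepl("\t", x$feature, fixed = TRUE)))
    stop("tabs are not allowed inside SGA fields", call. = FALSE)
  invisible(x)
}

.sga_order <- function(x) {
  order(x$chrom, x$position, .strand_rank(x$strand), method = "radix")
}

.check_sorted <- function(x) {
  identical(.sga_order(x), seq_len(nrow(x)))
}

#' Is an SGA stream flagged sorted?
#'
#' @param x an \code{sga} object.
#' @return logical.
#' @export
is_sorted <- function(x) isTRUE(attr(x, "sorted"))

#' Sort an SGA stream
#'
#' Orders records by chromosome (plain lexicographic byte order), position
#' and strand (\code{'+' < '-' < '0'}); ties beyond the full key keep their
#' input order (stable sort). The record multiset is unchanged.
#'
#' @param x an \code{sga} object.
#' @return a sorted \code{sga} object (flagged sorted).
#' @export
sort_records <- function(x) {
  .new_sga(as.data.frame(x)[.sga_order(x), , drop = FALSE], sorted = TRUE)
}

#' Merge sorted SGA streams
#'
#' k-way sort-merge of already-sorted streams into one sorted stream. Counts
#' are not combined (use \code{\link{compact}} for that); extra fields are
#' preserved. Records with fully tied keys appear in the order of the input
#' streams.
#'
#' @param ... \code{sga} objects, or a single list of them.
#' @return a sorted \code{sga} object.
#' @export
sort_merge <- function(...) {
  streams <- list(...)
  if (length(streams) == 1L && is.list(streams[[1]]) &&
      !inherits(streams[[1]], "sga"))
    streams <- streams[[1]]
  for (i in seq_along(streams)) {
    if (!inherits(streams[[i]], "sga"))
      stop("sort_merge inputs must be sga objects", call. = FALSE)
    if (!is_sorted(streams[[i]]))
      stop("sort_merge input ", i, " is not sorted", call. = FALSE)
  }
  merged <- do.call(rbind, lapply(streams, as.data.frame))
  if (is.null(merged)) return(sga())
  sort_records(.new_sga(merged, sorted = FALSE))
}

#' Compact an SGA stream
#'
#' Merges consecutive records identical in (chromosome, feature, position,
#' strand) into one record with the summed count; the extra fields of the
#' first record of each run are kept. Total count per key is conserved
#' exactly.
#'
#' @param x a sorted \code{sga} object.
#' @return a compacted, sorted \code{sga} object.
#' @export
compact <- function(x) {
  if (!is_sorted(x)) stop("compact requires a sorted SGA stream", call. = FALSE)
  n <- nrow(x)
  if (n <= 1L) return(x)
  same <- x$chrom[-1L] == x$chrom[-n] &
    x$feature[-1L] == x$feature[-n] &
    x$position[-1L] == x$position[-n] &
    x$strand[-1L] == x$strand[-n]
  grp <- cumsum(c(TRUE, !same))
  first <- which(c(TRUE, !same))
  out <- as.data.frame(x)[first, , drop = FALSE]
  out$count <- as.integer(rowsum(as.numeric(x$count), grp)[, 1L])
  .new_sga(out, sorted = TRUE)
}

# ---- I/O ---------------------------------------------------------------

#' Read an SGA file
#'
#' Parses a tab-delimited SGA file (five obligatory fields: chromosome,
#' feature, position, strand, count; any further fields are kept verbatim in
#' \code{extras}). Lines starting with \code{#} are skipped. Sortedness is
#' verified while reading and the returned stream flagged accordingly.
#'
#' @param file path or connection, or a character vector of lines via
#'   \code{text =}.
#' @param count_ceiling optional integer >= 1; counts above it are capped
#'   (with ceiling 1 this is equivalent to removing duplicate reads).
#' @param text character vector of SGA lines (alternative to \code{file}).
#' @return an \code{sga} object.
#' @export
read_sga <- function(file = NULL, count_ceiling = NULL, text = NULL) {
  if (!is.null(count_ceiling)) {
    count_ceiling <- as.integer(count_ceiling)
    if (is.na(count_ceiling) || count_ceiling < 1L)
      stop("count_ceiling must be an integer >= 1", call. = FALSE)
  }
  lines <- if (!is.null(text)) text else readLines(file)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) return(sga(sorted = TRUE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("SGA parse error at line ", lineno[which(nf < 5L)[1L]],
         ": expected >= 5 tab-delimited fields", call. = FALSE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- get(1L); feature <- get(2L)
  pos_chr <- get(3L); strand <- get(4L); cnt_chr <- get(5L)
  bad_int <- !grepl("^[0-9]+$", pos_chr) | !grepl("^[0-9]+$", cnt_chr)
  if (any(bad_int))
    stop("SGA parse error at line ", lineno[which(bad_int)[1L]],
         ": position and count must be non-negative integers", call. = FALSE)
  bad_strand <- !(strand %in% .STRANDS)
  if (any(bad_strand))
    stop("SGA parse error at line ", lineno[which(bad_strand)[1L]],
         ": strand must be one of +, -, 0", call. = FALSE)
  position <- as.integer(pos_chr); count <- as.integer(cnt_chr)
  bad_val <- position < 1L | count < 1L
  if (any(bad_val))
    stop("SGA validation error at line ", lineno[which(bad_val)[1L]],
         ": position and count must be >= 1", call. = FALSE)
  if (!is.null(count_ceiling)) count <- pmin(count, count_ceiling)
  extras <- vapply(fields, function(f)
    if (length(f) > 5L) paste(f[-(1:5)], collapse = "\t") else "",
    character(1))
  sga(chrom, feature, position, strand, count, extras)
}

#' Write an SGA file
#'
#' @param x an \code{sga} object.
#' @param file path or connection; when missing, the formatted lines are
#'   returned invisibly without writing.
#' @return the character vector of lines, invisibly.
#' @export
write_sga <- function(x, file = NULL) {
  lines <- paste(x$chrom, x$feature, x$position, x$strand, x$count, sep = "\t")
  has_extra <- nzchar(x$extras)
  lines[has_extra] <- paste(lines[has_extra], x$extras[has_extra], sep = "\t")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# ---- region sets -------------------------------------------------------

#' Construct a region set
#'
#' A region set holds per-chromosome 1-based closed intervals with a total
#' count and a feature label, as produced by the genome segmenter or read
#' from a "regions SGA" file where a \code{+} line marks the first base and
#' a \code{-} line the last base of each region.
#'
#' @param chrom,start,end,count,feature parallel vectors describing the
#'   regions (start and end are both inclusive).
#' @return an object of class \code{sga_regions} (a data frame), sorted by
#'   chromosome and start.
#' @export
sga_regions <- function(chrom = character(), start = integer(),
                        end = integer(), count = integer(),
                        feature = character()) {
  if (length(feature) == 1L) feature <- rep(feature, length(start))
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), count = as.integer(count),
                  feature = as.character(feature), stringsAsFactors = FALSE)
  if (any(x$start > x$end))
    stop("region start must be <= end", call. = FALSE)
  x <- x[order(x$chrom, x$start, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL
  if (nrow(x) > 1L) {
    same <- x$chrom[-1L] == x$chrom[-nrow(x)]
    if (any(same & x$start[-1L] <= x$end[-nrow(x)]))
      stop("regions within a chromosome must be disjoint", call. = FALSE)
  }
  structure(x, class = c("sga_regions", "data.frame"))
}

#' Serialize a region set as boundary-pair SGA records
#'
#' Each region becomes two SGA lines: a \code{+} line at its first base and
#' a \code{-} line at its last base; both carry the region's total count.
#'
#' @param regions an \code{sga_regions} object.
#' @return a sorted \code{sga} object of alternating boundary lines.
#' @export
regions_to_sga <- function(regions) {
  n <- nrow(regions)
  if (n == 0L) return(sga(sorted = TRUE))
  idx <- rep(seq_len(n), each = 2L)
  sga(chrom = regions$chrom[idx],
      feature = regions$feature[idx],
      position = as.vector(rbind(regions$start, regions$end)),
      strand = rep(c("+", "-"), n),
      count = regions$count[idx])
}

#' Parse boundary-pair SGA records into a region set
#'
#' Inverse of \code{\link{regions_to_sga}}: expects, per chromosome and
#' feature, strictly alternating \code{+}/\code{-} lines.
#'
#' @param x a sorted \code{sga} object of boundary lines.
#' @return an \code{sga_regions} object.
#' @export
sga_to_regions <- function(x) {
  if (!is_sorted(x)) x <- sort_records(x)
  strand <- x$strand
  if (nrow(x) %% 2L != 0L || any(strand[c(TRUE, FALSE)] != "+") ||
      any(strand[c(FALSE, TRUE)] != "-")) {
    bad <- which(strand != rep(c("+", "-"), length.out = nrow(x)))[1L]
    if (is.na(bad)) bad <- nrow(x)
    stop("unpaired region boundary at ", x$chrom[bad], ":", x$position[bad],
         call. = FALSE)
  }
  plus <- x[strand == "+", ]; minus <- x[strand == "-", ]
  if (any(plus$chrom != minus$chrom) || any(plus$position > minus$position)) {
    bad <- which(plus$chrom != minus$chrom | plus$position > minus$position)[1L]
    stop("unpaired region boundary at ", plus$chrom[bad], ":",
         plus$position[bad], call. = FALSE)
  }
  sga_regions(plus$chrom, plus$position, minus$position,
              plus$count, plus$feature)
}

# ---- genome table and chromosome aliases --------------------------------

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param file path or connection.
#' @return a named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  if (any(tab$length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  stats::setNames(as.numeric(tab$length), tab$chrom)
}

#' Read a chromosome-alias table
#'
#' Two tab-separated columns mapping UCSC-style names (e.g. \code{chr1}) to
#' versioned RefSeq accessions (e.g. \code{NC_000001.10}). The mapping must
#' be one-to-one.
#'
#' @param file path or connection.
#' @return a data frame with columns \code{ucsc} and \code{refseq}.
#' @export
read_chrom_alias <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("ucsc", "refseq"))
  if (anyDuplicated(tab$ucsc) || anyDuplicated(tab$refseq))
    stop("chromosome alias mapping must be one-to-one", call. = FALSE)
  tab
}

#' Rename chromosomes through an alias table
#'
#' Applies the UCSC <-> RefSeq mapping to an SGA stream and re-sorts
#' (renaming can change the lexicographic chromosome order). Names absent
#' from the table are left unchanged.
#'
#' @param x an \code{sga} object.
#' @param alias a data frame from \code{\link{read_chrom_alias}}.
#' @param to \code{"refseq"} or \code{"ucsc"}: the naming to convert to.
#' @return a sorted \code{sga} object.
#' @export
rename_chroms <- function(x, alias, to = c("refseq", "ucsc")) {
  to <- match.arg(to)
  from <- if (to == "refseq") alias$ucsc else alias$refseq
  dest <- if (to == "refseq") alias$refseq else alias$ucsc
  i <- match(x$chrom, from)
  df <- as.data.frame(x)
  df$chrom[!is.na(i)] <- dest[i[!is.na(i)]]
  sort_records(.new_sga(df, sorted = FALSE))
}

#' @export
as.data.frame.sga <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "sorted") <- NULL
  rownames(x) <- NULL
  x
}

#' @export
print.sga <- function(x, ...) {
  cat("SGA stream: ", nrow(x), " record(s)",
      if (is_sorted(x)) " (sorted)" else " (unsorted)", "\n", sep = "")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more\n", sep = "")
  invisible(x)
}
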