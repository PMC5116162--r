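# Synthetic ChIP-seq data with known ground truth: planted binding sites
# with a fragment-length read geometry plus Poisson background, and planted
# enriched domains over a depleted background. All randomness flows from a
# single integer seed, split deterministically per chromosome.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Simulate a ChIP-seq experiment
#'
#' Emulates the read geometry of a ChIP-seq assay: immunoprecipitated
#' fragments of length \code{fragment_length} centered near each binding
#' site (center jittered with a Gaussian of sd \code{jitter_sd}), sequenced
#' from a uniformly-chosen end, so plus-strand 5' tags cluster
#' \code{floor(L/2)} bp upstream and minus-strand tags the same distance
#' downstream of the site. Uniform Poisson background reads are added at
#' \code{background_rate} reads per bp. Reads jittered off the chromosome
#' are redrawn. Output is sorted and compacted; identical seeds give
#' identical output.
#'
#' @param genome named vector of chromosome lengths.
#' @param n_sites number of binding sites to plant (drawn uniformly away
#'   from the chromosome edges), ignored when \code{sites} is given.
#' @param sites optional data frame with columns \code{chrom},
#'   \code{position} of pre-chosen sites.
#' @param fragment_length mean fragment length L in bp (default 150).
#' @param jitter_sd sd of the fragment-center jitter in bp (default 20).
#' @param reads_per_site signal reads per site (default 10).
#' @param background_rate background reads per bp (default 0).
#' @param feature feature label (default \code{"CHIP"}).
#' @param seed integer seed.
#' @return a list with \code{sga} (sorted, compacted stream) and
#'   \code{truth} (data frame of site chrom/position/reads).
#' @export
simulate_chip <- function(genome, n_sites = NULL, sites = NULL,
                          fragment_length = 150L, jitter_sd = 20,
                          reads_per_site = 10L, background_rate = 0,
                          feature = "CHIP", seed = 1L) {
  stopifnot(fragment_length >= 1L, jitter_sd >= 0, background_rate >= 0)
  half <- fragment_length %/% 2L
  chroms <- names(genome)
  if (is.null(sites)) {
    if (is.null(n_sites)) stop("give either n_sites or sites", call. = FALSE)
    sites <- .with_seed(seed, {
      chr <- sample(chroms, n_sites, replace = TRUE,
                    prob = as.numeric(genome) / sum(as.numeric(genome)))
      margin <- fragment_length + 5 * jitter_sd
      pos <- vapply(chr, function(cc)
        as.integer(round(stats::runif(1, margin, genome[[cc]] - margin))),
        integer(1))
      data.frame(chrom = chr, position = pos, stringsAsFactors = FALSE)
    })
    sites <- sites[order(sites$chrom, sites$position), , drop = FALSE]
    rownames(sites) <- NULL
  }
  if (any(sites$position < 1L) ||
      any(sites$position > genome[sites$chrom]))
    stop("site outside chromosome bounds", call. = FALSE)
  recs <- list()
  for (i in seq_along(chroms)) {
    cc <- chroms[i]; len <- as.numeric(genome[[i]])
    recs[[i]] <- .with_seed(.split_seed(seed, i), {
      s <- sites$position[sites$chrom == cc]
      pos <- integer(0); std <- character(0)
      if (length(s) > 0L && reads_per_site > 0L) {
        site <- rep(s, each = reads_per_site)
        n <- length(site)
        center <- as.integer(round(site + stats::rnorm(n, 0, jitter_sd)))
        strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
        p <- ifelse(strand == "+", center - half, center + half)
        bad <- which(p < 1L | p > len)
        while (length(bad) > 0L) {       # redraw off-chromosome reads
          center <- as.integer(round(site[bad] +
                                       stats::rnorm(length(bad), 0, jitter_sd)))
          strand[bad] <- ifelse(stats::runif(length(bad)) < 0.5, "+", "-")
          p[bad] <- ifelse(strand[bad] == "+", center - half, center + half)
          bad <- bad[p[bad] < 1L | p[bad] > len]
        }
        pos <- p; std <- strand
      }
      nbg <- stats::rpois(1, background_rate * len)
      if (nbg > 0L) {
        pos <- c(pos, as.integer(ceiling(stats::runif(nbg, 0, len))))
        std <- c(std, ifelse(stats::runif(nbg) < 0.5, "+", "-"))
      }
      if (length(pos) == 0L) NULL else
        data.frame(chrom = cc, feature = feature, position = pos,
                   strand = std, count = 1L, extras = "",
                   stringsAsFactors = FALSE)
    })
  }
  recs <- do.call(rbind, recs)
  stream <- if (is.null(recs)) sga(sorted = TRUE) else
    compact(sort_records(.new_sga(recs, sorted = FALSE)))
  truth <- sites
  truth$reads <- reads_per_site
  list(sga = stream, truth = truth)
}

#' Simulate enriched domains over a depleted background
#'
#' Plants disjoint enriched intervals with a given read density (reads per
#' bp) on a uniform Poisson background covering the rest of each chromosome.
#' Read counts per region are Poisson with mean density x length; positions
#' uniform within the region; all records unoriented (strand \code{0}).
#'
#' @param genome named vector of chromosome lengths.
#' @param intervals data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{density} (reads per bp inside the interval); must be
#'   disjoint.
#' @param background_density reads per bp outside the intervals.
#' @param feature feature label (default \code{"DOM"}).
#' @param seed integer seed.
#' @return a list with \code{sga} (sorted, compacted stream) and
#'   \code{truth} (the intervals data frame).
#' @export
simulate_domains <- function(genome, intervals, background_density = 0,
                             feature = "DOM", seed = 1L) {
  stopifnot(all(intervals$density >= 0), background_density >= 0)
  ivl <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  if (nrow(ivl) > 1L) {
    same <- ivl$chrom[-1L] == ivl$chrom[-nrow(ivl)]
    if (any(same & ivl$start[-1L] <= ivl$end[-nrow(ivl)]))
      stop("planted intervals must be disjoint", call. = FALSE)
  }
  chroms <- names(genome)
  recs <- list()
  for (i in seq_along(chroms)) {
    cc <- chroms[i]; len <- as.numeric(genome[[i]])
    recs[[i]] <- .with_seed(.split_seed(seed, i), {
      iv <- ivl[ivl$chrom == cc, , drop = FALSE]
      # segment the chromosome into planted and background pieces
      pieces <- data.frame(start = integer(0), end = integer(0),
                           density = numeric(0))
      cursor <- 1L
      for (j in seq_len(nrow(iv))) {
        if (iv$start[j] > cursor)
          pieces <- rbind(pieces, data.frame(start = cursor,
                                             end = iv$start[j] - 1L,
                                             density = background_density))
        pieces <- rbind(pieces, data.frame(start = iv$start[j],
                                           end = iv$end[j],
                                           density = iv$density[j]))
        cursor <- iv$end[j] + 1L
      }
      if (cursor <= len)
        pieces <- rbind(pieces, data.frame(start = cursor, end = as.integer(len),
                                           density = background_density))
      pos <- integer(0)
      for (j in seq_len(nrow(pieces))) {
        plen <- pieces$end[j] - pieces$start[j] + 1
        nr <- stats::rpois(1, pieces$density[j] * plen)
        if (nr > 0L)
          pos <- c(pos, pieces$start[j] +
                     as.integer(floor(stats::runif(nr, 0, plen))))
      }
      if (length(pos) == 0L) NULL else
        data.frame(chrom = cc, feature = feature, position = pos,
                   strand = "0", count = 1L, extras = "",
                   stringsAsFactors = FALSE)
    })
  }
  recs <- do.call(rbind, recs)
  stream <- if (is.null(recs)) sga(sorted = TRUE) else
    compact(sort_records(.new_sga(recs, sorted = FALSE)))
  list(sga = stream, truth = ivl)
}
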