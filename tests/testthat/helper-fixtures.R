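# Random fixture builders used across the suite. All callers fix the seed.

random_sga <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000L,
                       features = "F", strands = c("+", "-", "0"),
                       max_count = 5L) {
  sort_records(sga(
    chrom = sample(chroms, n, replace = TRUE),
    feature = sample(features, n, replace = TRUE),
    position = sample.int(max_pos, n, replace = TRUE),
    strand = sample(strands, n, replace = TRUE),
    count = sample.int(max_count, n, replace = TRUE)))
}

# clustered tags: a few dense clusters over sparse background, the shape
# the peak caller is meant for
random_clustered_sga <- function(n_clusters = 4L, reads_per_cluster = 12L,
                                 n_background = 30L, span = 20000L,
                                 chroms = c("chr1", "chr2")) {
  recs <- lapply(chroms, function(chr) {
    centers <- sample.int(span - 400L, n_clusters) + 200L
    pos <- c(unlist(lapply(centers, function(cc)
               cc + as.integer(round(rnorm(reads_per_cluster, 0, 40))))),
             sample.int(span, n_background))
    pos <- pmax(1L, pos)
    data.frame(chrom = chr, feature = "F", position = pos, strand = "0",
               count = 1L, extras = "", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  compact(sort_records(sga(df$chrom, df$feature, df$position, df$strand,
                           df$count)))
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000L,
                           feature = "BLK") {
  per <- split(seq_len(n), sample(chroms, n, replace = TRUE))
  chrom <- character(0); start <- integer(0); end <- integer(0)
  for (chr in names(per)) {
    k <- length(per[[chr]])
    edges <- sort(sample.int(max_pos, 2L * k))
    s <- edges[c(TRUE, FALSE)]; e <- edges[c(FALSE, TRUE)]
    keep <- c(TRUE, s[-1L] > e[-k])      # enforce disjointness
    chrom <- c(chrom, rep(chr, sum(keep)))
    start <- c(start, s[keep]); end <- c(end, e[keep])
  }
  sga_regions(chrom, start, end, count = rep(1L, length(start)),
              feature = feature)
}

sga_text <- function(...) read_sga(text = c(...))
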