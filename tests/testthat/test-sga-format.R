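test_that("read_sga parses fields, extras, comments and the count ceiling", {
  x <- sga_text("chr1\tCTCF\t1000\t+\t3")
  expect_equal(as.data.frame(x),
               data.frame(chrom = "chr1", feature = "CTCF", position = 1000L,
                          strand = "+", count = 3L, extras = "",
                          stringsAsFactors = FALSE))
  capped <- read_sga(text = "chr1\tCTCF\t1000\t+\t7", count_ceiling = 1)
  expect_equal(capped$count, 1L)
  extra <- sga_text("chr1\tTSS\t5\t0\t1\tNM_0001")
  expect_equal(extra$extras, "NM_0001")
  two_extra <- sga_text("chr1\tTSS\t5\t0\t1\tNM_0001\tscore9")
  expect_equal(two_extra$extras, "NM_0001\tscore9")
  commented <- read_sga(text = c("# header", "chr1\tF\t1\t0\t1"))
  expect_equal(nrow(commented), 1L)
})

test_that("read_sga rejects malformed lines with the offending line number", {
  expect_error(read_sga(text = "chr1\tF\t10\t+"), "line 1")
  expect_error(read_sga(text = c("chr1\tF\t10\t+\t1", "chr1\tF\tx\t+\t1")),
               "line 2")
  expect_error(read_sga(text = "chr1\tF\t10\t*\t1"), "strand")
  expect_error(read_sga(text = "chr1\tF\t0\t+\t1"), ">= 1")
  expect_error(read_sga(text = "chr1\tF\t10\t+\t0"), ">= 1")
  expect_error(sga("chr1", "", 1L, "+", 1L), "non-empty")
})

test_that("sort_records orders by chromosome, position and strand", {
  x <- sga(c("chr2", "chr1"), "F", c(1L, 9L), c("+", "-"), 1L)
  expect_equal(sort_records(x)$chrom, c("chr1", "chr2"))
  y <- sga("chr1", "F", c(100L, 100L), c("0", "+"), 1L)
  expect_equal(sort_records(y)$strand, c("+", "0"))
  expect_true(is_sorted(sort_records(y)))
})

test_that("sorting a shuffled sorted fixture restores it (full-key oracle)", {
  set.seed(11)
  ref <- random_sga(400)
  shuffled <- as.data.frame(ref)[sample.int(nrow(ref)), ]
  redone <- sort_records(sga(shuffled$chrom, shuffled$feature,
                             shuffled$position, shuffled$strand,
                             shuffled$count, shuffled$extras))
  # independent full-key sort (includes feature/count to cancel tie ambiguity)
  key <- function(d) order(d$chrom, d$position, match(d$strand, c("+", "-", "0")),
                           d$feature, d$count, method = "radix")
  expect_equal(as.data.frame(redone)[key(redone), ],
               as.data.frame(ref)[key(ref), ], ignore_attr = TRUE)
})

test_that("sort_merge merges sorted streams and rejects unsorted input", {
  a <- sga_text("chr1\tA\t10\t+\t1")
  b <- sga_text("chr1\tB\t5\t+\t1")
  m <- sort_merge(a, b)
  expect_equal(m$position, c(5L, 10L))
  expect_equal(sort_merge(a, sga())$position, a$position)
  unsorted <- sga(c("chr1", "chr1"), "F", c(9L, 1L), "0", 1L)
  expect_false(is_sorted(unsorted))
  expect_error(sort_merge(a, unsorted), "not sorted")
  set.seed(21)
  s1 <- random_sga(1000, features = "A")
  s2 <- random_sga(1000, features = "B")
  oracle <- sort_records(sga(c(s1$chrom, s2$chrom), c(s1$feature, s2$feature),
                             c(s1$position, s2$position),
                             c(s1$strand, s2$strand),
                             c(s1$count, s2$count)))
  expect_equal(as.data.frame(sort_merge(s1, s2)), as.data.frame(oracle),
               ignore_attr = TRUE)
})

test_that("compact merges identical keys, conserves counts, keeps extras", {
  x <- sga_text("chr1\tF\t10\t0\t2", "chr1\tF\t10\t0\t3")
  expect_equal(as.data.frame(compact(x))$count, 5L)
  y <- sga_text("chr1\tF\t10\t0\t2", "chr1\tG\t10\t0\t3")
  expect_equal(nrow(compact(y)), 2L)
  z <- sga_text("chr1\tF\t10\t0\t2\tkeepme", "chr1\tF\t10\t0\t3\tdropme")
  expect_equal(compact(z)$extras, "keepme")
  expect_error(compact(sga(c("chr1", "chr1"), "F", c(9L, 1L), "0", 1L,
                           sorted = FALSE)), "sorted")
  # per-key totals match a hash-map accumulation oracle (merging is
  # consecutive-only, so interleaved features may keep several records per
  # key; the totals must still agree)
  set.seed(31)
  r <- random_sga(800, max_pos = 50L, features = c("A", "B"))
  cp <- compact(r)
  key <- function(d) paste(d$chrom, d$feature, d$position, d$strand)
  oracle <- tapply(r$count, key(r), sum)
  totals <- tapply(cp$count, key(cp), sum)
  expect_equal(as.numeric(totals[names(oracle)]), as.numeric(oracle))
  expect_equal(sum(cp$count), sum(r$count))
  k <- key(cp)
  expect_false(any(k[-1L] == k[-length(k)]))  # no consecutive duplicates left
})

test_that("region sets round-trip through boundary-pair SGA lines", {
  reg <- sga_regions(c("chr1", "chr1"), c(100L, 500L), c(200L, 600L),
                     c(50L, 7L), "SEG")
  pairs <- regions_to_sga(reg)
  expect_equal(pairs$strand, c("+", "-", "+", "-"))
  expect_equal(pairs$count, c(50L, 50L, 7L, 7L))
  back <- sga_to_regions(pairs)
  expect_equal(as.data.frame(back), as.data.frame(reg), ignore_attr = TRUE)
  expect_error(sga_regions("chr1", 10L, 5L, 1L, "S"), "start")
  expect_error(sga_regions(c("chr1", "chr1"), c(10L, 15L), c(20L, 30L),
                           1L, "S"), "disjoint")
  broken <- sga_text("chr1\tS\t100\t+\t1", "chr1\tS\t200\t+\t1")
  expect_error(sga_to_regions(broken), "chr1:200")
})

test_that("chromosome alias renaming is applied before sorting", {
  alias <- data.frame(ucsc = c("chr1", "chr2"),
                      refseq = c("NC_000001.10", "NC_000002.11"))
  x <- sga_text("chr1\tF\t10\t+\t1", "chr2\tF\t5\t+\t1")
  r <- rename_chroms(x, alias, to = "refseq")
  expect_equal(r$chrom, c("NC_000001.10", "NC_000002.11"))
  expect_true(is_sorted(r))
  expect_equal(rename_chroms(r, alias, to = "ucsc")$chrom, c("chr1", "chr2"))
})

test_that("sga files round-trip through write_sga/read_sga", {
  set.seed(41)
  x <- random_sga(200)
  df <- as.data.frame(x)
  df$extras[1:10] <- "geneX\t0.5"
  x <- sort_records(sga(df$chrom, df$feature, df$position, df$strand,
                        df$count, df$extras))
  f <- withr::local_tempfile(fileext = ".sga")
  write_sga(x, f)
  expect_equal(as.data.frame(read_sga(f)), as.data.frame(x),
               ignore_attr = TRUE)
})
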