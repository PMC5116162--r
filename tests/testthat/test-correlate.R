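merged_fixture <- function() {
  sort_records(sga_text(
    "chr1\tR\t1000\t+\t1",
    "chr1\tT\t950\t0\t1",
    "chr1\tT\t1050\t0\t2"))
}

test_that("correlate_profile bins target counts around references", {
  p <- correlate_profile(merged_fixture(), "R", "T", -100, 100, 50)
  expect_equal(p$value, c(0, 1, 0, 2))
  expect_equal(p$offset, c(-100, -50, 0, 50))
  expect_equal(p$n_ref, 1)
  expect_equal(p$total_target, 3)
})

test_that("oriented mode negates offsets for minus-strand references", {
  x <- sort_records(sga_text(
    "chr1\tR\t1000\t-\t1",
    "chr1\tT\t950\t0\t1",
    "chr1\tT\t1050\t0\t2"))
  p <- correlate_profile(x, "R", "T", -100, 100, 50, oriented = TRUE)
  # offsets d = r - t: target 1050 -> d = -50 (bin [-50,0)), 950 -> d = +50
  expect_equal(p$value, c(0, 2, 0, 1))
  expect_equal(p$value, oracle_profile(x, "R", "T", -100, 100, 50,
                                       oriented = TRUE))
})

test_that("density and ratio normalizations rescale the count profile", {
  p <- correlate_profile(merged_fixture(), "R", "T", -100, 100, 50,
                         normalization = "density")
  expect_equal(p$value, c(0, 1, 0, 2) / 50)
  genome <- c(chr1 = 10000)
  r <- correlate_profile(merged_fixture(), "R", "T", -100, 100, 50,
                         normalization = "ratio", genome = genome)
  expect_equal(r$value, (c(0, 1, 0, 2) / 50) / (3 / 10000))
  expect_warning(
    correlate_profile(merged_fixture(), "R", "T", -100, 100, 50,
                      normalization = "ratio"),
    "estimating genome length")
})

test_that("reference multiplicity: a count-k reference equals k duplicated lines", {
  set.seed(71)
  base <- random_sga(150, features = c("R", "T"))
  df <- as.data.frame(base)
  dup <- df[rep(seq_len(nrow(df)), df$count), ]
  dup$count <- 1L
  dup_sga <- sort_records(sga(dup$chrom, dup$feature, dup$position,
                              dup$strand, dup$count))
  p1 <- correlate_profile(base, "R", "T", -200, 200, 40)
  p2 <- correlate_profile(dup_sga, "R", "T", -200, 200, 40)
  expect_equal(p1$value, p2$value)
  expect_equal(p1$n_ref, p2$n_ref)
})

test_that("profile parameters are validated and missing features named", {
  x <- merged_fixture()
  expect_error(correlate_profile(x, "R", "T", 100, -100, 50), "begin")
  expect_error(correlate_profile(x, "R", "T", -100, 100, 30), "divisible")
  expect_error(correlate_profile(x, "R", "NOPE", -100, 100, 50), "NOPE")
})

test_that("extract_matrix resolves bins per reference with profile-consistent sums", {
  x <- sort_records(sga_text(
    "chr1\tR\t1000\t0\t1", "chr1\tR\t5000\t0\t1", "chr1\tT\t1050\t0\t2"))
  m <- extract_matrix(x, "R", "T", -100, 100, 100)
  expect_equal(unname(m), rbind(c(0L, 2L), c(0L, 0L)), ignore_attr = TRUE)
  expect_equal(rownames(m), c("chr1:1000:0", "chr1:5000:0"))
  p <- correlate_profile(x, "R", "T", -100, 100, 100)
  expect_equal(colSums(m), p$value, ignore_attr = TRUE)
  # no targets in range -> all-zero matrix with one row per reference
  far <- sort_records(sga_text("chr1\tR\t1000\t0\t1", "chr1\tT\t9000\t0\t1"))
  m0 <- extract_matrix(far, "R", "T", -100, 100, 100)
  expect_equal(unname(m0), rbind(c(0L, 0L)), ignore_attr = TRUE)
})

test_that("score_references appends window counts and honors the threshold", {
  x <- sort_records(sga_text(
    "chr1\tR\t1000\t+\t1\tgeneX",
    "chr1\tT\t990\t0\t3", "chr1\tT\t1100\t0\t2"))
  s <- score_references(x, "R", "T", -50, 50)
  expect_equal(s$extras, "geneX\t3")
  expect_equal(nrow(score_references(x, "R", "T", -50, 50, threshold = 4)), 0L)
  s0 <- score_references(x, "R", "T", -50, 50, threshold = 0)
  expect_equal(nrow(s0), 1L)
  expect_equal(s0$position, 1000L)
})

test_that("sweep implementations match the brute-force oracle on random fixtures", {
  set.seed(72)
  for (rep in 1:40) {
    x <- random_sga(200, features = c("R", "T"), max_pos = 3000L)
    oriented <- rep %% 2L == 0L
    b <- sample(c(-300L, -150L, 0L), 1L)
    w <- sample(c(10L, 50L, 75L), 1L)
    e <- b + w * sample(3:8, 1L)
    p <- correlate_profile(x, "R", "T", b, e, w, oriented = oriented)
    expect_equal(p$value, oracle_profile(x, "R", "T", b, e, w,
                                         oriented = oriented))
    m <- extract_matrix(x, "R", "T", b, e, w, oriented = oriented)
    expect_equal(unname(m), unname(oracle_matrix(x, "R", "T", b, e, w,
                                                 oriented = oriented)),
                 ignore_attr = TRUE)
    s <- score_references(x, "R", "T", b, e, oriented = oriented)
    appended <- as.numeric(vapply(strsplit(s$extras, "\t"), function(f)
      f[length(f)], character(1)))
    expect_equal(appended, oracle_score(x, "R", "T", b, e,
                                        oriented = oriented))
  }
})

test_that("count-mode bin totals equal count-weighted reference scores", {
  set.seed(73)
  x <- random_sga(300, features = c("R", "T"))
  b <- -120L; e <- 120L; w <- 40L
  p <- correlate_profile(x, "R", "T", b, e, w)
  s <- score_references(x, "R", "T", b, e)
  appended <- as.numeric(vapply(strsplit(s$extras, "\t"), function(f)
    f[length(f)], character(1)))
  expect_equal(sum(p$value), sum(appended * s$count))
})

test_that("oriented mirror: flipped references reverse the profile over the mirrored range", {
  set.seed(74)
  for (rep in 1:10) {
    # oriented references must carry a strand: use +/- refs only
    refs <- random_sga(80, features = "R", strands = c("+", "-"))
    tgts <- random_sga(170, features = "T")
    x <- sort_merge(refs, tgts)
    df <- as.data.frame(x)
    flip <- df
    flip$strand[flip$feature == "R"] <-
      chartr("+-", "-+", flip$strand[flip$feature == "R"])
    xf <- sort_records(sga(flip$chrom, flip$feature, flip$position,
                           flip$strand, flip$count))
    b <- -200L; e <- 120L; w <- 40L
    fwd <- correlate_profile(x, "R", "T", b, e, w, oriented = TRUE)
    # integer offsets: bin [b+jw, b+(j+1)w) of the flipped profile collects
    # raw offsets in (-(b+(j+1)w), -(b+jw)], i.e. the reversed bins of the
    # unflipped profile over the mirrored half-open range [-e+1, -b+1)
    rev_prof <- correlate_profile(xf, "R", "T", -e + 1L, -b + 1L, w,
                                  oriented = TRUE)
    expect_equal(fwd$value, rev(rev_prof$value))
  }
})
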