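toy_ta <- function() ta_index(c(chr = "GATTACA"))

test_that("track_from_positions accumulates reads at TA sites", {
  ta <- toy_ta()
  tr <- track_from_positions(
    tibble::tibble(replicon_id = "chr", pos = c(3L, 3L), reads = c(5, 2)), ta
  )
  expect_equal(tr$count, 7)
  expect_warning(
    tr2 <- track_from_positions(
      tibble::tibble(replicon_id = "chr", pos = 0L, reads = 1), ta
    ),
    "non-TA"
  )
  expect_equal(tr2$count, 0)
  empty <- track_from_positions(
    tibble::tibble(replicon_id = character(), pos = integer(),
                   reads = numeric()), ta
  )
  expect_equal(empty$count, 0)
  expect_error(
    track_from_positions(
      tibble::tibble(replicon_id = "chr", pos = 99L, reads = 1), ta
    ),
    "outside"
  )
})

test_that("wig reading converts 1-based positions and fills zeros", {
  ta <- toy_ta()
  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr", "4 7"), wig)
  tr <- read_track(wig, ta)
  expect_equal(tr$pos, 3L)
  expect_equal(tr$count, 7)
  # header-only file is an all-zero track
  empty <- withr::local_tempfile(fileext = ".wig")
  writeLines("variableStep chrom=chr", empty)
  expect_equal(read_track(empty, ta)$count, 0)
  # duplicate position lines are summed with a warning
  dup <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr", "4 7", "4 2"), dup)
  expect_warning(trd <- read_track(dup, ta), "duplicate")
  expect_equal(trd$count, 9)
  bad <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("not a wig", "4 7"), bad)
  expect_error(read_track(bad, ta), "malformed")
})

test_that("write_track / read_track round-trips counts", {
  genome <- c(chr = strrep("GATTACA", 20))
  ta <- ta_index(genome)
  set.seed(3)
  tr <- tibble::tibble(replicon_id = "chr", library_id = "x", pos = ta$pos,
                       count = rpois(nrow(ta), 2))
  wig <- withr::local_tempfile(fileext = ".wig")
  write_track(tr, wig)
  back <- read_track(wig, ta, library_id = "x")
  expect_equal(back$count, tr$count)
})

test_that("combine_libraries sums counts and is commutative/associative", {
  ta <- ta_index(c(chr = "TATATA"))
  mk <- function(cnt, id) tibble::tibble(replicon_id = "chr", library_id = id,
                                         pos = ta$pos, count = cnt)
  a <- mk(c(0, 2, 0), "a")
  b <- mk(c(1, 0, 0), "b")
  c_ <- mk(c(5, 1, 2), "c")
  expect_equal(combine_libraries(list(a, b))$count, c(1, 2, 0))
  expect_equal(combine_libraries(list(a))$count, a$count)
  expect_equal(combine_libraries(list(a, b, c_))$count,
               combine_libraries(list(c_, b, a))$count)
  expect_equal(
    combine_libraries(list(combine_libraries(list(a, b)), c_))$count,
    combine_libraries(list(a, combine_libraries(list(b, c_))))$count
  )
  set.seed(9)
  for (i in 1:10) {
    x <- mk(rbinom(3, 1, 0.5) * rpois(3, 4), "x")
    y <- mk(rbinom(3, 1, 0.5) * rpois(3, 4), "y")
    comb <- combine_libraries(list(x, y))
    expect_gte(mean(comb$count > 0),
               max(mean(x$count > 0), mean(y$count > 0)))
  }
  bad <- mk(c(1, 1, 1), "bad")[1:2, ]
  expect_error(combine_libraries(list(a, bad)), "TA universes")
  expect_error(combine_libraries(list()), "no tracks")
})

test_that("TTR normalization is scale-invariant, idempotent, outlier-robust", {
  set.seed(5)
  n <- 1000
  tr <- tibble::tibble(replicon_id = "r", library_id = "l",
                       pos = (seq_len(n) - 1L) * 16L,
                       count = rbinom(n, 1, 0.8) * rpois(n, 50))
  one <- ttr_normalize(tr)
  twice <- ttr_normalize(one)
  expect_equal(one$count, twice$count, tolerance = 1e-9)
  doubled <- tr
  doubled$count <- tr$count * 2
  expect_equal(ttr_normalize(doubled)$count, one$count, tolerance = 1e-9)
  expect_equal(one$count == 0, tr$count == 0)
  # a single huge outlier barely moves the scale factor (it is trimmed away)
  spiked <- tr
  spiked$count[which(tr$count > 0)[1]] <- 1000 * max(tr$count)
  f_plain <- one$count[tr$count > 0][2] / tr$count[tr$count > 0][2]
  sp <- ttr_normalize(spiked)
  i <- which(tr$count > 0)[2]
  f_spiked <- sp$count[i] / spiked$count[i]
  expect_lt(abs(f_spiked - f_plain) / f_plain, 0.01)
  zero <- tr
  zero$count <- 0
  expect_error(ttr_normalize(zero), "all-zero")
})

test_that("LOESS correction flattens positional trends, keeps zeros", {
  n <- 600
  pos <- (seq_len(n) - 1L) * 16L
  flat <- tibble::tibble(replicon_id = "r", library_id = "l", pos = pos,
                         count = 40)
  out <- loess_correct(flat)
  expect_equal(out$count, flat$count, tolerance = 1e-6)
  set.seed(8)
  grad <- flat
  grad$count <- rpois(n, 20 * (1 + seq(0, 1, length.out = n)))  # 2x gradient
  grad$count[sample(n, 60)] <- 0
  corr <- loess_correct(grad)
  expect_equal(corr$count == 0, grad$count == 0)
  slope <- coef(lm(corr$count ~ pos))[2]
  expect_lt(abs(slope * max(pos)), 0.05 * 2 * mean(corr$count))
  expect_error(loess_correct(flat[1:10, ]), "50")
})

test_that("library_qc reports totals, density, and the 50% QC flag", {
  tr <- dplyr::bind_rows(
    tibble::tibble(replicon_id = "r", library_id = "good",
                   pos = (0:9) * 16L, count = c(rep(4, 8), 0, 0)),
    tibble::tibble(replicon_id = "r", library_id = "poor",
                   pos = (0:9) * 16L, count = c(rep(2, 3), rep(0, 7)))
  )
  qc <- library_qc(tr)
  expect_equal(qc$density[qc$library_id == "good"], 0.8)
  expect_equal(qc$qc_pass, c(TRUE, FALSE))
  expect_equal(qc$total_reads[qc$library_id == "poor"], 6)
})
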