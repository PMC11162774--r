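# Frameshift-assay arithmetic: methionine normalisation, percent/ratio,
# activity, replicate summaries, and the translation helper.

test_that("intensities are normalised by internal methionine counts", {
  a <- normalized_amounts(90, 30, 9, 6)
  expect_equal(a$amount_full, 10)
  expect_equal(a$amount_fs, 5)
  expect_equal(normalized_amounts(50, 0, 5, 3)$amount_fs, 0)
  eq <- normalized_amounts(42, 42, 7, 7)
  expect_equal(eq$amount_full, eq$amount_fs)
  expect_error(normalized_amounts(10, 10, 0, 3),
    class = "riboframe_validation_error")
  expect_error(normalized_amounts(-1, 10, 2, 3),
    class = "riboframe_validation_error")
})

test_that("percent and ratio reproduce the published worked examples", {
  # percent 33.8 -> ratio 0.51; percent 55.4 -> ratio 1.24 at 2 dp
  r1 <- frameshift_stats(100 - 33.8, 33.8)
  expect_equal(r1$percent_fs, 33.8)
  expect_equal(round(r1$ratio_fs, 2), 0.51)
  r2 <- frameshift_stats(100 - 55.4, 55.4)
  expect_equal(round(r2$ratio_fs, 2), 1.24)
  r0 <- frameshift_stats(12, 0)
  expect_equal(r0$percent_fs, 0)
  expect_equal(r0$ratio_fs, 0)
  expect_true(is.infinite(frameshift_stats(0, 5)$ratio_fs))
  expect_error(frameshift_stats(0, 0), class = "riboframe_validation_error")
})

test_that("the identity ratio = p / (100 - p) holds exactly per replicate", {
  withr::local_seed(11)
  full <- stats::runif(50, 0.1, 10)
  fs <- stats::runif(50, 0, 10)
  st <- frameshift_stats(full, fs)
  expect_equal(st$ratio_fs, st$percent_fs / (100 - st$percent_fs),
    tolerance = 1e-9)
})

test_that("activity is the total product relative to the control lane", {
  expect_equal(activity(6, 4, 6, 4), 1)
  expect_equal(activity(0, 0, 5, 5), 0)
  # constructed to give 0.71
  expect_equal(activity(5, 2.1, 8, 2), 0.71)
  expect_error(activity(1, 1, 0, 0), class = "riboframe_validation_error")
})

test_that("internal methionines exclude position 1 and reject bad alphabets", {
  expect_equal(count_internal_met("MAMKM"), 2L)
  expect_equal(count_internal_met("MAAA"), 0L)
  expect_equal(count_internal_met(c("M", "AM", "MM")), c(0L, 1L, 1L))
  expect_error(count_internal_met("MAX1"), class = "riboframe_validation_error")
})

test_that("count_internal_met agrees with a brute-force scan on random sequences", {
  withr::local_seed(12)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(1:1000, function(i) {
    paste(sample(alphabet, sample(1:60, 1), replace = TRUE), collapse = "")
  }, character(1))
  brute <- vapply(seqs, function(s) {
    n <- 0L
    for (k in 2:max(2, nchar(s))) {
      if (k <= nchar(s) && substr(s, k, k) == "M") n <- n + 1L
    }
    n
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(count_internal_met(seqs), brute)
})

test_that("0-frame and -1-frame products match an independent translation", {
  skip_if_not_installed("Biostrings")
  # start AUG; slippery GAAAAAAG ends codon 5 (position 15); stops in both frames
  m <- paste0("AUG", "GCU", "AUG", "G", "AAAAAAG", "CAU", "GCU", "UAA",
    "CCUAA")
  p <- fs_products(m, start = 1, slip_end = 15)
  expect_equal(p$protein_0, oracle_translate(substr(chartr("U", "T", m), 1,
    nchar(m))))
  # oracle for the -1 frame: codons to the slip, then re-read from slip_end
  dna <- chartr("U", "T", m)
  expect_equal(p$protein_m1,
    paste0(oracle_translate(substr(dna, 1, 15)),
      oracle_translate(substr(dna, 15, nchar(dna)))))
  # methionine counts of the two products match the brute-force translation
  oracle0 <- oracle_translate(dna)
  oracle1 <- paste0(oracle_translate(substr(dna, 1, 15)),
    oracle_translate(substr(dna, 15, nchar(dna))))
  expect_equal(count_internal_met(c(p$protein_0, p$protein_m1)),
    count_internal_met(c(oracle0, oracle1)))
  # the -1 product terminates prematurely relative to the 0-frame product
  expect_lt(nchar(p$protein_m1), nchar(p$protein_0))
})

test_that("replicate summaries give mean and sd/sqrt(N)", {
  res <- tibble::tibble(
    construct = rep(c("wt", "mut"), c(3, 2)),
    replicate = c(1:3, 1:2),
    percent_fs = c(50, 50, 50, 40, 60),
    ratio_fs = c(1, 1, 1, 40 / 60, 60 / 40)
  )
  sm <- fs_summarize(res)
  wt <- sm[sm$construct == "wt", ]
  expect_equal(wt$mean_ratio_fs, 1)
  expect_equal(wt$sem_ratio_fs, 0)
  mut <- sm[sm$construct == "mut", ]
  expect_equal(mut$mean_percent_fs, 50)
  expect_equal(mut$sem_percent_fs, 10)
  expect_error(fs_summarize(res[1, ]), class = "riboframe_validation_error")
})

test_that("summaries average per-replicate ratios, not the ratio of mean percents", {
  res <- tibble::tibble(
    construct = "x", replicate = 1:2,
    percent_fs = c(20, 60),
    ratio_fs = c(20 / 80, 60 / 40)
  )
  sm <- fs_summarize(res)
  expect_equal(sm$mean_ratio_fs, (0.25 + 1.5) / 2)
  implied <- sm$mean_percent_fs / (100 - sm$mean_percent_fs)
  expect_false(isTRUE(all.equal(sm$mean_ratio_fs, implied)))
})

test_that("a seeded replicate set matches brute-force mean and SEM", {
  withr::local_seed(13)
  vals <- stats::runif(8, 0.3, 1.5)
  res <- tibble::tibble(construct = "x", replicate = 1:8,
    percent_fs = 100 * vals / (1 + vals), ratio_fs = vals)
  sm <- fs_summarize(res)
  expect_equal(sm$mean_ratio_fs, sum(vals) / 8)
  expect_equal(sm$sem_ratio_fs,
    sqrt(sum((vals - mean(vals))^2) / 7) / sqrt(8))
})

test_that("the tidy pipeline is scale invariant and joins construct tables", {
  lanes <- tibble::tibble(
    construct = rep(c("ctrl", "mut"), each = 2),
    replicate = rep(1:2, 2),
    intensity_full = c(90, 80, 60, 55),
    intensity_fs = c(30, 28, 40, 42)
  )
  constructs <- tibble::tibble(construct = c("ctrl", "mut"),
    n_met_full = 9L, n_met_fs = 6L)
  q1 <- fs_quantify(lanes, constructs, control = "ctrl")
  lanes2 <- lanes |>
    dplyr::mutate(intensity_full = intensity_full * 7.3,
      intensity_fs = intensity_fs * 7.3)
  q2 <- fs_quantify(lanes2, constructs, control = "ctrl")
  expect_equal(q1$percent_fs, q2$percent_fs)
  expect_equal(q1$ratio_fs, q2$ratio_fs)
  expect_equal(q1$activity, q2$activity)
  expect_equal(q1$activity[q1$construct == "ctrl"], c(1, 1))

  sm <- fs_summarize(q1)
  expect_s3_class(autoplot(sm), "ggplot")
  ft <- fs_format_table(sm)
  expect_match(ft$ratio_fs[1], "^[0-9.]+ ± [0-9.]+$")
})

test_that("construct tables may supply sequences instead of counts", {
  skip_if_not_installed("Biostrings")
  lanes <- tibble::tibble(construct = "x", replicate = 1:2,
    intensity_full = c(20, 22), intensity_fs = c(10, 9))
  constructs <- tibble::tibble(construct = "x",
    seq_full = "MAMKMW", seq_fs = "MAMW")
  q <- fs_quantify(lanes, constructs)
  expect_equal(q$amount_full, c(20, 22) / 2)
  expect_equal(q$amount_fs, c(10, 9) / 1)
})
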