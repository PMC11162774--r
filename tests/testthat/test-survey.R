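# End-to-end survey pipeline on synthetic batches, the confidence filter,
# and the aggregation identities.

make_batch_config <- function(combos, seeds, ...) {
  ref <- make_synthetic_ribosome("classical", "retracted", seed = 1)$reference
  structs <- list()
  truth <- list()
  for (i in seq_along(combos)) {
    syn <- make_synthetic_ribosome(combos[[i]][1], combos[[i]][2],
      seed = seeds[i], ...)
    id <- sprintf("S%02d", i)
    structs[[id]] <- list(structure = syn$structure)
    truth[[id]] <- syn
  }
  list(config = survey_config(reference = ref, structures = structs),
    truth = truth)
}

test_that("a mixed synthetic batch reproduces every generator label", {
  combos <- list(
    c("classical", "intercalated"), c("classical", "retracted"),
    c("hybrid", "stacked"), c("hybrid", "retracted"),
    c("chimeric_hybrid", "intercalated"), c("chimeric_hybrid", "intercalated")
  )
  bc <- make_batch_config(combos, seeds = 30 + seq_along(combos))
  rec <- run_survey(names(bc$config$structures), bc$config)
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$confidence == "pass"))
  for (i in seq_len(nrow(rec))) {
    tr <- bc$truth[[rec$pdb_id[i]]]
    expect_equal(rec$state[i], tr$state)
    expect_equal(rec$call[i], tr$contact)
    expect_equal(rec$body_angle[i], tr$body_angle, tolerance = 0.05)
    expect_equal(rec$head_angle[i], tr$head_angle, tolerance = 0.05)
  }
  expect_true(all(rec$partners[rec$call == "intercalated"] == "-1|-2"))

  tab <- aggregate_survey(rec)
  expect_equal(tab$total, c(2, 2, 2))
  expect_equal(tab$n_intercalated[tab$state == "chimeric_hybrid"], 2)
  expect_equal(tab$positions[tab$state == "chimeric_hybrid"], "-1|-2")
  # conservation identity per row
  expect_equal(tab$total, tab$n_intercalated + tab$n_stacked + tab$n_retracted)
})

test_that("one unreadable file fails in isolation and reruns are byte-identical", {
  bc <- make_batch_config(list(c("classical", "stacked")), seeds = 41)
  bc$config$structures[["BAD"]] <- list(path = "/nonexistent/file.cif")
  ids <- c("S01", "BAD")
  rec1 <- run_survey(ids, bc$config)
  expect_equal(rec1$confidence, c("pass", "fail"))
  expect_match(rec1$fail_reason[2], "not found")
  rec2 <- run_survey(ids, bc$config)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  readr::write_tsv(rec1, f1)
  readr::write_tsv(rec2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empty accession lists are rejected", {
  bc <- make_batch_config(list(c("classical", "stacked")), seeds = 42)
  expect_error(run_survey(character(0), bc$config),
    class = "riboframe_validation_error")
})

test_that("the confidence filter gates on resolution, ring completeness, register", {
  syn <- make_synthetic_ribosome("classical", "stacked", seed = 43)
  cm <- identify_chains(syn$structure)
  reg <- locate_p_codon(syn$structure, cm)
  expect_true(confidence_filter(syn$structure, cm, reg)$pass)

  lowres <- make_synthetic_ribosome("classical", "stacked", seed = 43,
    resolution = 6.5)
  expect_equal(confidence_filter(lowres$structure, cm, reg)$reason, "resolution")

  broken <- make_synthetic_ribosome("classical", "stacked", seed = 43,
    drop_mrna_position = -2L)
  cmb <- identify_chains(broken$structure)
  regb <- locate_p_codon(broken$structure, cmb)
  expect_equal(confidence_filter(broken$structure, cmb, regb)$reason,
    "mrna_incomplete")

  expect_equal(confidence_filter(syn$structure, cm, NULL)$reason,
    "register_unresolved")
})

test_that("failed records carry no state or contact claims in aggregates", {
  rec <- as_records(dplyr::bind_rows(
    make_record("A", "classical", "stacked"),
    make_record("B", NA_character_, NA_character_, confidence = "fail",
      fail_reason = "resolution")
  ))
  tab <- aggregate_survey(rec)
  expect_equal(sum(tab$total), 1)
  expect_equal(attr(tab, "n_failed"), 1)
})

test_that("aggregation reproduces the expected row shapes", {
  chimeric <- lapply(1:18, function(i) {
    make_record(sprintf("C%02d", i), "chimeric_hybrid", "intercalated", "-1|-2")
  })
  hybrid <- lapply(1:7, function(i) {
    make_record(sprintf("H%02d", i), "hybrid", "retracted")
  })
  rec <- as_records(dplyr::bind_rows(c(chimeric, hybrid)))
  tab <- aggregate_survey(rec)
  ch <- tab[tab$state == "chimeric_hybrid", ]
  expect_equal(ch$total, 18)
  expect_equal(ch$n_intercalated, 18)
  expect_equal(ch$positions, "-1|-2")
  expect_equal(ch$pct_intercalated, 100)
  expect_equal(ch$n_stacked + ch$n_retracted, 0)
  hy <- tab[tab$state == "hybrid", ]
  expect_equal(hy$total, 7)
  expect_equal(hy$n_intercalated, 0)
  expect_equal(hy$pct_retracted, 100)
  expect_equal(tab$total, tab$n_intercalated + tab$n_stacked + tab$n_retracted)
})

test_that("unresolved contacts and unassigned states are tallied separately", {
  rec <- as_records(dplyr::bind_rows(
    make_record("A", "classical", "stacked"),
    make_record("B", "classical", "unresolved"),
    make_record("C", "unassigned", "stacked")
  ))
  tab <- aggregate_survey(rec)
  expect_equal(sum(tab$total), 1)
  expect_equal(attr(tab, "n_unresolved_contact"), 1)
  expect_equal(attr(tab, "n_unassigned_state"), 1)
  g <- glance(tab)
  expect_equal(g$n_pass, 3)
})

test_that("aggregation is invariant under record order and rejects empty surveys", {
  rec <- as_records(dplyr::bind_rows(
    make_record("A", "classical", "stacked"),
    make_record("B", "hybrid", "retracted"),
    make_record("C", "chimeric_hybrid", "intercalated", "-1|-2")
  ))
  t1 <- aggregate_survey(rec)
  t2 <- aggregate_survey(as_records(rec[c(3, 1, 2), ]))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  none <- as_records(make_record("A", NA_character_, NA_character_,
    confidence = "fail", fail_reason = "resolution"))
  expect_error(aggregate_survey(none), class = "riboframe_validation_error")
})

test_that("every scatter point appears in exactly one table row", {
  rec <- as_records(dplyr::bind_rows(
    make_record("A", "classical", "stacked"),
    make_record("B", "hybrid", "retracted"),
    make_record("C", "chimeric_hybrid", "intercalated", "-1|-2"),
    make_record("D", NA_character_, NA_character_, confidence = "fail",
      fail_reason = "resolution")
  ))
  sc <- fig_scatter(rec)
  tab <- aggregate_survey(rec)
  expect_equal(nrow(sc), 3)
  expect_equal(sum(tab$total), nrow(sc))
})

test_that("report files are written and record the threshold provenance", {
  bc <- make_batch_config(list(c("chimeric_hybrid", "intercalated")), seeds = 44)
  rec <- run_survey("S01", bc$config)
  dir <- withr::local_tempdir()
  write_survey_reports(rec, dir)
  expect_true(all(file.exists(file.path(dir,
    c("records.tsv", "table1.tsv", "fig2_scatter.csv", "survey_log.txt")))))
  log <- readLines(file.path(dir, "survey_log.txt"))
  expect_true(any(grepl("d_stack=4.5", log)))
  tab <- readr::read_tsv(file.path(dir, "table1.tsv"), show_col_types = FALSE)
  expect_equal(tab$total[tab$state == "chimeric_hybrid"], 1)
})

test_that("autoplot methods return ggplot objects", {
  rec <- as_records(dplyr::bind_rows(
    make_record("A", "classical", "stacked"),
    make_record("B", "chimeric_hybrid", "intercalated", "-1|-2")
  ))
  expect_s3_class(autoplot(rec), "ggplot")
  expect_s3_class(autoplot(aggregate_survey(rec)), "ggplot")
})
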