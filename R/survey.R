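# Batch pipeline: per accession, read -> identify chains -> mRNA register ->
# contact call for A1503 (optionally C1397) -> rotation state, with a
# declared confidence filter standing in for per-map visual inspection.
# Failures are recorded per structure and never abort the batch.

#' Survey configuration
#'
#' Assembles the configuration consumed by [run_survey()]. Per-structure
#' blocks override everything the heuristics would guess.
#'
#' @param reference The classical-state reference: either a
#'   [ribosome_structure()] or a list with `path` (and optionally `model`,
#'   `chains`).
#' @param structures Named list (by accession) of per-structure blocks; each
#'   may contain `path` or `structure`, `model`, `chains` (hints for
#'   [identify_chains()]), `numbering_offset_16S`, `p_codon_start`,
#'   `direction`.
#' @param thresholds Contact thresholds ([contact_thresholds()]).
#' @param windows State windows ([state_windows()]).
#' @param domains Domain definition ([domain_definition()]).
#' @param r_max Resolution cutoff of the confidence filter (angstrom).
#' @param pairing_cutoff P-codon detection cutoff (angstrom).
#' @param query_residue 16S residue screened against the mRNA (E. coli
#'   numbering; default 1503).
#' @param mrna_window Paper positions considered as contact candidates.
#' @param c1397 Also screen C1397 against downstream positions +6..+11.
#' @return A `survey_config` list.
#' @export
survey_config <- function(reference, structures = list(),
                          thresholds = contact_thresholds(),
                          windows = state_windows(),
                          domains = domain_definition(),
                          r_max = 4.0, pairing_cutoff = 3.5,
                          query_residue = 1503L,
                          mrna_window = c(-6:-1, 1:3),
                          c1397 = FALSE) {
  structure(
    list(reference = reference, structures = structures,
      thresholds = thresholds, windows = windows, domains = domains,
      r_max = r_max, pairing_cutoff = pairing_cutoff,
      query_residue = as.integer(query_residue), mrna_window = mrna_window,
      c1397 = c1397),
    class = "survey_config"
  )
}

#' Read a survey configuration from YAML
#'
#' The YAML mirrors [survey_config()]: top-level `reference: {path: ...}`,
#' `structures: {ID: {path: ..., chains: ..., p_codon_start: ...}}`, and
#' optional scalar overrides of the thresholds, windows and filter cutoffs.
#'
#' @param path YAML file path.
#' @return A `survey_config`.
#' @export
read_survey_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configuration requires the yaml package")
  }
  y <- yaml::read_yaml(path)
  th <- do.call(contact_thresholds, y$thresholds %||% list())
  wn <- do.call(state_windows, y$windows %||% list())
  survey_config(
    reference = y$reference,
    structures = y$structures %||% list(),
    thresholds = th, windows = wn,
    r_max = y$r_max %||% 4.0,
    pairing_cutoff = y$pairing_cutoff %||% 3.5,
    query_residue = y$query_residue %||% 1503L,
    c1397 = isTRUE(y$c1397)
  )
}

config_hash <- function(config) {
  rlang::hash(config[c("thresholds", "windows", "r_max", "pairing_cutoff",
    "query_residue", "mrna_window", "c1397")])
}

load_entry <- function(entry, default_id = "structure") {
  if (inherits(entry, "ribosome_structure")) return(entry)
  if (!is.null(entry$structure)) return(entry$structure)
  if (is.null(entry$path)) {
    abort(sprintf("no path or in-memory structure for %s", default_id),
      class = "riboframe_validation_error")
  }
  read_structure(entry$path, model = entry$model %||% 1L, pdb_id = default_id)
}

#' Confidence filter for a surveyed structure
#'
#' Declared, reproducible stand-in for per-map inspection: a structure passes
#' when its reported resolution is at most `r_max`, the query base and the
#' mRNA bases at positions -4..+1 each retain at least 5 canonical ring
#' atoms, and the mRNA register resolved.
#'
#' @param s A [ribosome_structure()].
#' @param cm Chain map (or `NULL` to identify).
#' @param reg Register, or `NULL` when it could not be resolved.
#' @param r_max Resolution cutoff (angstrom).
#' @param query_residue 16S residue number (file numbering).
#' @return List with `pass` (logical) and `reason` (string, `""` on pass).
#' @export
confidence_filter <- function(s, cm = NULL, reg = NULL, r_max = 4.0,
                              query_residue = 1503L) {
  if (is.na(s$resolution) || s$resolution > r_max) {
    return(list(pass = FALSE, reason = "resolution"))
  }
  cm <- cm %||% tryCatch(identify_chains(s), error = function(e) NULL)
  if (is.null(cm)) return(list(pass = FALSE, reason = "chains_unresolved"))
  q_ok <- tryCatch(
    {
      base_geometry(s, cm$rrna16S, query_residue)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!q_ok) return(list(pass = FALSE, reason = "query_incomplete"))
  if (is.null(reg)) return(list(pass = FALSE, reason = "register_unresolved"))
  for (p in c(-4L, -3L, -2L, -1L, 1L)) {
    ok <- tryCatch(
      {
        base_geometry(s, cm$mrna, register_residue(reg, p))
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) return(list(pass = FALSE, reason = "mrna_incomplete"))
  }
  list(pass = TRUE, reason = "")
}

empty_record <- function(pdb_id, reason) {
  tibble(
    pdb_id = pdb_id, confidence = "fail", fail_reason = reason,
    state = NA_character_, body_angle = NA_real_, head_angle = NA_real_,
    body_sign = NA_character_, head_sign = NA_character_,
    fit_rmsd_body = NA_real_, fit_rmsd_head = NA_real_,
    call = NA_character_, partners = NA_character_,
    d1 = NA_real_, d2 = NA_real_, alpha1 = NA_real_, alpha2 = NA_real_,
    min_distance = NA_real_, contact_flags = NA_character_,
    c1397_call = NA_character_, c1397_partners = NA_character_,
    resolution = NA_real_, method = NA_character_,
    config_hash = NA_character_
  )
}

survey_one_structure <- function(id, config, ref, cm_ref) {
  entry <- config$structures[[id]] %||% list()
  s <- load_entry(entry, id)
  hints <- entry$chains %||% NULL
  if (!is.null(entry$numbering_offset_16S)) {
    hints <- c(hints %||% list(),
      list(numbering_offset_16S = entry$numbering_offset_16S))
  }
  cm <- identify_chains(s, hints)
  off <- cm$numbering_offset_16S
  reg <- tryCatch(
    locate_p_codon(s, cm, pairing_cutoff = config$pairing_cutoff,
      p_codon_start = entry$p_codon_start, direction = entry$direction %||% 1L),
    riboframe_register_error = function(e) NULL
  )
  q_res <- config$query_residue + off
  conf <- confidence_filter(s, cm, reg, r_max = config$r_max,
    query_residue = q_res)
  if (!conf$pass) {
    rec <- empty_record(id, conf$reason)
    rec$resolution <- s$resolution
    rec$method <- s$method
    rec$config_hash <- config_hash(config)
    return(rec)
  }

  geoms <- mrna_base_geometries(s, cm, reg, config$mrna_window)
  q <- tryCatch(base_geometry(s, cm$rrna16S, q_res), error = function(e) NULL)
  cc <- classify_contact(q, geoms, config$thresholds)

  c1397_call <- NA_character_
  c1397_partners <- NA_character_
  if (isTRUE(config$c1397)) {
    g2 <- mrna_base_geometries(s, cm, reg, c(6:11))
    q2 <- tryCatch(base_geometry(s, cm$rrna16S, 1397L + off),
      error = function(e) NULL)
    cc2 <- classify_contact(q2, g2, config$thresholds)
    c1397_call <- cc2$call
    c1397_partners <- format_partners(cc2$partners)
  }

  m <- measure_rotations(s, ref, dd = config$domains, cm = cm, cm_ref = cm_ref)
  st <- classify_state(m, config$windows)

  tidy_cc <- tidy(cc)
  tibble(
    pdb_id = id, confidence = "pass", fail_reason = "",
    state = st$state, body_angle = m$body_angle, head_angle = m$head_angle,
    body_sign = m$body_sign, head_sign = m$head_sign,
    fit_rmsd_body = m$fit_rmsd_body, fit_rmsd_head = m$fit_rmsd_head,
    call = cc$call, partners = tidy_cc$partners,
    d1 = tidy_cc$d1, d2 = tidy_cc$d2,
    alpha1 = tidy_cc$alpha1, alpha2 = tidy_cc$alpha2,
    min_distance = tidy_cc$min_distance, contact_flags = tidy_cc$flags,
    c1397_call = c1397_call, c1397_partners = c1397_partners,
    resolution = s$resolution, method = s$method,
    config_hash = config_hash(config)
  )
}

#' Run the survey pipeline over a list of accessions
#'
#' For each accession: read the structure, identify chains, resolve the mRNA
#' register, apply the confidence filter, classify the query-base contact,
#' measure rotation against the reference and assign a conformational state.
#' Per-structure failures yield a failed record (with reason) and never abort
#' the batch; the run is deterministic given identical inputs and
#' configuration.
#'
#' @param ids Character vector of accessions (keys into
#'   `config$structures`).
#' @param config A [survey_config()] or path to a YAML file for
#'   [read_survey_config()].
#' @return A `survey_records` tibble, one row per accession.
#' @export
run_survey <- function(ids, config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_survey_config(config)
  }
  stopifnot(inherits(config, "survey_config"))
  if (length(ids) == 0) {
    abort("empty accession list", class = "riboframe_validation_error")
  }
  ref <- load_entry(config$reference, "reference")
  cm_ref <- identify_chains(ref,
    if (is.list(config$reference)) config$reference$chains else NULL)
  records <- list_rbind(map(ids, function(id) {
    tryCatch(
      survey_one_structure(id, config, ref, cm_ref),
      error = function(e) empty_record(id, conditionMessage(e))
    )
  }))
  class(records) <- c("survey_records", class(records))
  attr(records, "thresholds") <- config$thresholds
  attr(records, "windows") <- config$windows
  records
}

#' Aggregate survey records into a state-by-contact summary table
#'
#' Confident records only; per conformational state the table reports the
#' total, the intercalated/stacked/retracted counts and percentages, and the
#' modal intercalation position pair. Structures with an unresolved contact
#' call or an unassigned state are tallied separately (attributes
#' `n_unresolved_contact`, `n_unassigned_state`, `n_failed`), so each row
#' satisfies total = intercalated + stacked + retracted.
#'
#' @param records A `survey_records` tibble from [run_survey()].
#' @return A `survey_table` tibble (one row per state).
#' @export
aggregate_survey <- function(records) {
  pass <- records |> filter(.data$confidence == "pass")
  if (nrow(pass) == 0) {
    abort("no record passed the confidence filter; empty survey",
      class = "riboframe_validation_error")
  }
  usable <- pass |> filter(.data$state != "unassigned", .data$call != "unresolved")
  states <- c("classical", "hybrid", "chimeric_hybrid")
  tab <- list_rbind(map(states, function(st) {
    g <- usable |> filter(.data$state == st)
    n_int <- sum(g$call == "intercalated")
    modal <- if (n_int > 0) {
      names(sort(table(g$partners[g$call == "intercalated"]), decreasing = TRUE))[1]
    } else {
      ""
    }
    tot <- nrow(g)
    pct <- function(k) if (tot > 0) 100 * k / tot else NA_real_
    tibble(
      state = st, total = tot,
      n_intercalated = n_int, positions = modal, pct_intercalated = pct(n_int),
      n_stacked = sum(g$call == "stacked"), pct_stacked = pct(sum(g$call == "stacked")),
      n_retracted = sum(g$call == "retracted"),
      pct_retracted = pct(sum(g$call == "retracted"))
    )
  }))
  class(tab) <- c("survey_table", class(tab))
  attr(tab, "n_pass") <- nrow(pass)
  attr(tab, "n_failed") <- sum(records$confidence == "fail")
  attr(tab, "n_unassigned_state") <- sum(pass$state == "unassigned")
  attr(tab, "n_unresolved_contact") <- sum(pass$call == "unresolved")
  tab
}

#' @method glance survey_table
#' @export
glance.survey_table <- function(x, ...) {
  tibble(
    n_pass = attr(x, "n_pass"),
    n_failed = attr(x, "n_failed"),
    n_unassigned_state = attr(x, "n_unassigned_state"),
    n_unresolved_contact = attr(x, "n_unresolved_contact"),
    n_intercalated = sum(x$n_intercalated),
    n_stacked = sum(x$n_stacked),
    n_retracted = sum(x$n_retracted)
  )
}

#' Rotation scatter export (body vs head angle, symbol = contact call)
#'
#' @param records A `survey_records` tibble.
#' @return Tibble of confident records: `pdb_id`, `body_angle`,
#'   `head_angle`, `call`, `state`.
#' @export
fig_scatter <- function(records) {
  records |>
    filter(.data$confidence == "pass") |>
    select("pdb_id", "body_angle", "head_angle", "call", "state")
}

#' Write survey reports to a directory
#'
#' Emits `records.tsv` (per-structure report including the threshold
#' provenance hash), `table1.tsv` (the aggregated state-by-contact table with
#' display-rounded percentages), `fig2_scatter.csv` and `survey_log.txt`
#' (threshold/window values, counts).
#'
#' @param records A `survey_records` tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_reports <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(records, file.path(dir, "records.tsv"))
  tab <- aggregate_survey(records)
  out <- tab |>
    mutate(across(dplyr::starts_with("pct_"), ~ round(.x)))
  readr::write_tsv(out, file.path(dir, "table1.tsv"))
  readr::write_csv(fig_scatter(records), file.path(dir, "fig2_scatter.csv"))
  th <- attr(records, "thresholds")
  wn <- attr(records, "windows")
  log_lines <- c(
    "riboframe survey log",
    sprintf("records: %d (pass %d, fail %d)", nrow(records),
      sum(records$confidence == "pass"), sum(records$confidence == "fail")),
    if (!is.null(th)) sprintf("thresholds: %s",
      paste(names(th), unlist(th), sep = "=", collapse = " ")),
    if (!is.null(wn)) sprintf("windows: %s",
      paste(names(wn), vapply(wn, paste, "", collapse = ".."), sep = "=",
        collapse = " "))
  )
  writeLines(log_lines, file.path(dir, "survey_log.txt"))
  invisible(dir)
}
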