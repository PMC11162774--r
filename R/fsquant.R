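# Quantification arithmetic for the in vitro -1 programmed frameshifting
# assay: band intensities of the full-length (27 kDa) and premature-
# termination (16 kDa) products are normalised by the number of internal
# methionines of each predicted product ([35S]-Met labelling), then expressed
# as percent frameshift, -1/0-frame ratio and translation activity relative
# to a control construct. Inputs are assumed background-corrected upstream.

#' Count internal methionines of a protein sequence
#'
#' Counts `M` residues excluding position 1 (the initiator, which is labelled
#' but shared by both products and conventionally excluded).
#'
#' @param sequence Character vector of protein sequences over the 20-letter
#'   amino-acid alphabet (`*` allowed as a trailing stop).
#' @return Integer vector of counts.
#' @export
count_internal_met <- function(sequence) {
  seq_clean <- sub("\\*$", "", toupper(sequence))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seq_clean)
  if (any(bad)) {
    abort(paste0("invalid amino-acid characters in sequence(s): ",
      paste(which(bad), collapse = ", ")), class = "riboframe_validation_error")
  }
  vapply(seq_clean, function(s) {
    if (nchar(s) <= 1) return(0L)
    sum(strsplit(substr(s, 2, nchar(s)), "")[[1]] == "M")
  }, integer(1), USE.NAMES = FALSE)
}

#' Methionine-normalised product amounts
#'
#' @param intensity_full,intensity_fs Band intensities (arbitrary units,
#'   >= 0) of the full-length and frameshifted products.
#' @param n_met_full,n_met_fs Internal methionine counts (>= 1).
#' @return Tibble with `amount_full`, `amount_fs`.
#' @export
normalized_amounts <- function(intensity_full, intensity_fs, n_met_full,
                               n_met_fs) {
  if (any(c(n_met_full, n_met_fs) < 1)) {
    abort("methionine counts must be >= 1", class = "riboframe_validation_error")
  }
  if (any(c(intensity_full, intensity_fs) < 0) ||
    !all(is.finite(c(intensity_full, intensity_fs)))) {
    abort("intensities must be finite and >= 0", class = "riboframe_validation_error")
  }
  tibble(amount_full = intensity_full / n_met_full,
    amount_fs = intensity_fs / n_met_fs)
}

#' Percent frameshift and -1/0-frame ratio
#'
#' `percent_fs = 100 * fs / (fs + full)`; `ratio_fs = fs / full` (flagged
#' infinite when the full-length amount is zero). The per-replicate identity
#' `ratio = percent / (100 - percent)` holds exactly.
#'
#' @param amount_full,amount_fs Methionine-normalised amounts.
#' @return Tibble with `percent_fs`, `ratio_fs`.
#' @export
frameshift_stats <- function(amount_full, amount_fs) {
  total <- amount_full + amount_fs
  if (any(total <= 0)) {
    abort("total product is zero; frameshift level undefined",
      class = "riboframe_validation_error")
  }
  tibble(
    percent_fs = 100 * amount_fs / total,
    ratio_fs = ifelse(amount_full > 0, amount_fs / amount_full, Inf)
  )
}

#' Translation activity relative to a control lane
#'
#' Activity is the methionine-normalised total product (full-length plus
#' frameshifted) as a fraction of the control lane's total.
#'
#' @param amount_full,amount_fs Amounts for the lane under test.
#' @param control_full,control_fs Amounts for the control lane.
#' @return Numeric vector of fractions.
#' @export
activity <- function(amount_full, amount_fs, control_full, control_fs) {
  ctrl <- control_full + control_fs
  if (any(ctrl <= 0)) {
    abort("control total must be > 0", class = "riboframe_validation_error")
  }
  (amount_full + amount_fs) / ctrl
}

#' Per-replicate frameshift quantification of a lane table
#'
#' Tidy entry point: joins lane intensities with per-construct methionine
#' counts, normalises, and computes per-replicate percent frameshift, ratio
#' and (when `control` is given) activity relative to the control construct
#' within the same replicate.
#'
#' @param lanes Tibble with columns `construct`, `replicate`,
#'   `intensity_full`, `intensity_fs`.
#' @param constructs Tibble with `construct` and either `n_met_full`,
#'   `n_met_fs` or protein sequences `seq_full`, `seq_fs` (counted with
#'   [count_internal_met()]).
#' @param control Name of the control construct, or `NULL` to skip activity.
#' @return Tibble: one row per lane with `amount_full`, `amount_fs`,
#'   `percent_fs`, `ratio_fs` and optionally `activity`.
#' @export
fs_quantify <- function(lanes, constructs, control = NULL) {
  needed <- c("construct", "replicate", "intensity_full", "intensity_fs")
  if (!all(needed %in% names(lanes))) {
    abort(paste0("lanes must have columns: ", paste(needed, collapse = ", ")),
      class = "riboframe_validation_error")
  }
  if (!all(c("n_met_full", "n_met_fs") %in% names(constructs))) {
    if (all(c("seq_full", "seq_fs") %in% names(constructs))) {
      constructs <- constructs |>
        mutate(n_met_full = count_internal_met(.data$seq_full),
          n_met_fs = count_internal_met(.data$seq_fs))
    } else {
      abort("constructs must carry n_met_full/n_met_fs or seq_full/seq_fs",
        class = "riboframe_validation_error")
    }
  }
  df <- lanes |>
    left_join(constructs |> select("construct", "n_met_full", "n_met_fs"),
      by = "construct")
  if (any(is.na(df$n_met_full))) {
    abort(paste0("constructs table is missing: ",
      paste(unique(df$construct[is.na(df$n_met_full)]), collapse = ", ")),
      class = "riboframe_validation_error")
  }
  amounts <- normalized_amounts(df$intensity_full, df$intensity_fs,
    df$n_met_full, df$n_met_fs)
  stats <- frameshift_stats(amounts$amount_full, amounts$amount_fs)
  out <- dplyr::bind_cols(df, amounts, stats)
  if (!is.null(control)) {
    if (!control %in% out$construct) {
      abort(sprintf("control construct '%s' not in lanes", control),
        class = "riboframe_validation_error")
    }
    ctrl <- out |>
      filter(.data$construct == control) |>
      select("replicate", control_full = "amount_full",
        control_fs = "amount_fs")
    out <- out |>
      left_join(ctrl, by = "replicate") |>
      mutate(activity = activity(.data$amount_full, .data$amount_fs,
        .data$control_full, .data$control_fs)) |>
      select(-"control_full", -"control_fs")
  }
  as_tibble(out)
}

#' Summarise replicate frameshift results per construct
#'
#' Arithmetic mean and standard error (sample sd / sqrt(N)) of each
#' per-replicate quantity. Note the mean of per-replicate ratios is not the
#' ratio implied by the mean percent; both are reported per replicate first
#' and averaged here, matching how replicate assays are conventionally
#' summarised.
#'
#' @param results Tibble from [fs_quantify()].
#' @return An `fs_summary` tibble: per construct `n`, `mean_percent_fs`,
#'   `sem_percent_fs`, `mean_ratio_fs`, `sem_ratio_fs` and (when present)
#'   `mean_activity`, `sem_activity`.
#' @export
fs_summarize <- function(results) {
  counts <- results |> dplyr::count(.data$construct)
  if (any(counts$n < 2)) {
    abort(paste0("SEM undefined for construct(s) with fewer than 2 replicates: ",
      paste(counts$construct[counts$n < 2], collapse = ", ")),
      class = "riboframe_validation_error")
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  vars <- intersect(c("percent_fs", "ratio_fs", "activity"), names(results))
  out <- results |>
    group_by(.data$construct) |>
    summarise(
      n = n(),
      across(dplyr::all_of(vars),
        list(mean = mean, sem = sem), .names = "{.fn}_{.col}"),
      .groups = "drop"
    )
  class(out) <- c("fs_summary", class(out))
  out
}

#' Display-rounded frameshift summary table
#'
#' Formats an [fs_summarize()] result with the conventional
#' `value +/- sem` columns at two-decimal (ratio, activity) or one-decimal
#' (percent) display precision; full precision stays in the `fs_summary`.
#'
#' @param summary An `fs_summary` tibble.
#' @return Tibble of formatted strings, one row per construct.
#' @export
fs_format_table <- function(summary) {
  fmt <- function(m, s, digits) {
    sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, s)
  }
  out <- tibble(
    construct = summary$construct,
    percent_fs = fmt(summary$mean_percent_fs, summary$sem_percent_fs, 1),
    ratio_fs = fmt(summary$mean_ratio_fs, summary$sem_ratio_fs, 2)
  )
  if ("mean_activity" %in% names(summary)) {
    out$activity <- fmt(summary$mean_activity, summary$sem_activity, 2)
  }
  out
}

#' Translate the 0-frame and -1-frame products of an mRNA
#'
#' Helper for predicting the two polypeptides of a programmed -1
#' frameshifting construct: the 0-frame product runs from `start` to the
#' first in-frame stop; the -1-frame product translates in frame up to the
#' end of the slippery sequence, then slips one nucleotide backward and
#' continues in the -1 frame to its first stop. Translation uses the
#' standard genetic code via Biostrings.
#'
#' @param mrna mRNA sequence (A/C/G/U or T).
#' @param start 1-based position of the start codon.
#' @param slip_end 1-based position of the last base of the slippery
#'   sequence (slippage site).
#' @return List with `protein_0` and `protein_m1` (no stop character).
#' @export
fs_products <- function(mrna, start, slip_end) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("fs_products requires the Biostrings package")
  }
  dna <- chartr("Uu", "Tt", toupper(mrna))
  if ((slip_end - start + 1) %% 3 != 0) {
    abort("slip_end must close a codon of the 0 frame",
      class = "riboframe_validation_error")
  }
  translate_to_stop <- function(seqs) {
    n <- nchar(seqs) - nchar(seqs) %% 3
    if (n == 0) return("")
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seqs, 1, n)), no.init.codon = TRUE))
    sub("\\*.*$", "", aa)
  }
  p0 <- translate_to_stop(substr(dna, start, nchar(dna)))
  head_aa <- translate_to_stop(substr(dna, start, slip_end))
  # after the -1 slip the next codon re-reads the last slippery base
  tail_aa <- translate_to_stop(substr(dna, slip_end, nchar(dna)))
  list(protein_0 = p0, protein_m1 = paste0(head_aa, tail_aa))
}
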