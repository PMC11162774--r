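# Reading coordinate files, identifying functional chains, and anchoring the
# mRNA position register at the P-site codon (+1 = first base of the P codon;
# negative positions run 5' into the E site, there is no position 0).

NUCLEOTIDE_RESIDUES <- unique(c(
  PURINE_RESIDUES, PYRIMIDINE_RESIDUES,
  c("I", "DI", "N", "UNK")
))

#' Construct a ribosome structure object
#'
#' The container used throughout the package: a tibble of atoms plus file
#' metadata. Usually produced by [read_structure()] or the synthetic
#' generators rather than called directly.
#'
#' @param atoms Tibble with columns `chain`, `resno` (integer), `insert`
#'   (character, `""` when absent), `resid` (residue name, e.g. `"A"`),
#'   `elety` (atom name, e.g. `"P"`, `"N1"`), `x`, `y`, `z` (angstrom).
#' @param pdb_id Accession or label for the structure.
#' @param resolution Reported resolution in angstrom, or `NA`.
#' @param method One of `"xray"`, `"cryoem"`, `"other"`.
#' @param model Model number the atoms were taken from.
#' @return An object of class `ribosome_structure`.
#' @export
ribosome_structure <- function(atoms, pdb_id = "unknown", resolution = NA_real_,
                               method = "other", model = 1L) {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "riboframe_validation_error")
  }
  if (nrow(atoms) == 0) {
    abort("structure has no atoms", class = "riboframe_validation_error")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("structure contains non-finite coordinates",
      class = "riboframe_validation_error")
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  structure(
    list(
      pdb_id = pdb_id,
      atoms = atoms[needed],
      resolution = resolution,
      method = method,
      model = as.integer(model)
    ),
    class = "ribosome_structure"
  )
}

#' @export
print.ribosome_structure <- function(x, ...) {
  chains <- unique(x$atoms$chain)
  cat(sprintf(
    "<ribosome_structure> %s: %d atoms, %d chain(s) [%s], model %d, %s, resolution %s\n",
    x$pdb_id, nrow(x$atoms), length(chains),
    paste(head(chains, 8), collapse = ","), x$model, x$method,
    ifelse(is.na(x$resolution), "NA", sprintf("%.2f A", x$resolution))
  ))
  invisible(x)
}

#' @method as_tibble ribosome_structure
#' @export
as_tibble.ribosome_structure <- function(x, ...) x$atoms

# residues of one chain in file order (resno, then insertion code)
chain_residues <- function(s, chain_id) {
  s$atoms |>
    filter(.data$chain == chain_id) |>
    distinct(.data$resno, .data$insert, .data$resid) |>
    arrange(.data$resno, .data$insert)
}

atoms_of_residue <- function(s, chain_id, resno, insert = "") {
  s$atoms[s$atoms$chain == chain_id & s$atoms$resno == resno &
    s$atoms$insert == insert, , drop = FALSE]
}

# ---- file reading -----------------------------------------------------------

guess_format <- function(path, lines) {
  if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)) return("cif")
  if (grepl("\\.(pdb|ent)(\\.gz)?$", path, ignore.case = TRUE)) return("pdb")
  if (any(grepl("^_atom_site\\.", lines))) return("cif")
  if (any(grepl("^(ATOM|HETATM)", lines))) return("pdb")
  abort(paste0(path, ": neither an mmCIF _atom_site block nor PDB ATOM records found"),
    class = "riboframe_format_error")
}

# locate the _atom_site loop in mmCIF text: returns header field names and the
# line indices of its data rows
cif_atom_site_block <- function(lines) {
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) {
    abort("mmCIF file has no _atom_site loop", class = "riboframe_format_error")
  }
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  start <- max(hdr_idx) + 1
  rows <- integer(0)
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
      startsWith(ln, "loop_") || startsWith(ln, "data_")) {
      break
    }
    rows <- c(rows, i)
  }
  list(fields = fields, rows = rows)
}

# keep only the requested model's atom rows (mmCIF); returns possibly
# rewritten lines
cif_select_model <- function(lines, model, path) {
  blk <- cif_atom_site_block(lines)
  mcol <- which(blk$fields == "pdbx_PDB_model_num")
  if (length(mcol) == 0) {
    if (model != 1) {
      abort(sprintf("%s: model %d requested but file has no model numbering", path, model),
        class = "riboframe_model_error")
    }
    return(lines)
  }
  toks <- strsplit(trimws(lines[blk$rows]), "\\s+")
  models <- vapply(toks, function(t) t[[mcol]], character(1))
  present <- unique(models)
  if (!as.character(model) %in% present) {
    abort(sprintf("%s: model %d not present (models: %s)", path, model,
      paste(present, collapse = ", ")), class = "riboframe_model_error")
  }
  if (length(present) == 1) return(lines)
  drop <- blk$rows[models != as.character(model)]
  lines[-drop]
}

pdb_select_model <- function(lines, model, path) {
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) == 0) {
    if (model != 1) {
      abort(sprintf("%s: model %d requested but file has a single model", path, model),
        class = "riboframe_model_error")
    }
    return(lines)
  }
  nums <- as.integer(sub("^MODEL\\s+", "", lines[model_starts]))
  hit <- which(nums == model)
  if (length(hit) == 0) {
    abort(sprintf("%s: model %d not present (models: %s)", path, model,
      paste(nums, collapse = ", ")), class = "riboframe_model_error")
  }
  start <- model_starts[hit]
  ends <- grep("^ENDMDL", lines)
  end <- min(ends[ends > start], length(lines))
  keep <- c(lines[seq_len(model_starts[1] - 1)], lines[(start + 1):(end - 1)])
  keep
}

extract_header_meta <- function(lines, format) {
  res <- NA_real_
  method <- "other"
  grab <- function(pattern) {
    m <- regmatches(lines, regexec(pattern, lines))
    hits <- m[vapply(m, length, integer(1)) == 2]
    if (length(hits) > 0) hits[[1]][2] else NA_character_
  }
  if (format == "cif") {
    for (tag in c(
      "_reflns\\.d_resolution_high\\s+([0-9.]+)",
      "_refine\\.ls_d_res_high\\s+([0-9.]+)",
      "_em_3d_reconstruction\\.resolution\\s+([0-9.]+)"
    )) {
      v <- grab(tag)
      if (!is.na(v)) {
        res <- as.numeric(v)
        break
      }
    }
    mm <- grab("_exptl\\.method\\s+'?([^'\n]+)'?")
    if (!is.na(mm)) {
      method <- if (grepl("X-RAY", mm, ignore.case = TRUE)) "xray"
        else if (grepl("MICROSCOPY|CRYO", mm, ignore.case = TRUE)) "cryoem"
        else "other"
    }
  } else {
    v <- grab("^REMARK   2 RESOLUTION\\.\\s+([0-9.]+)")
    if (!is.na(v)) res <- as.numeric(v)
    mm <- grab("^EXPDTA\\s+(.+)$")
    if (!is.na(mm)) {
      method <- if (grepl("X-RAY", mm, ignore.case = TRUE)) "xray"
        else if (grepl("MICROSCOPY|CRYO", mm, ignore.case = TRUE)) "cryoem"
        else "other"
    }
  }
  list(resolution = res, method = method)
}

#' Read a ribosome structure from an mmCIF or PDB file
#'
#' Coordinate parsing is delegated to bio3d; the requested model is selected
#' before parsing (bio3d keeps only the first model of multi-model files) and
#' resolution/method are pulled from the header when present.
#'
#' @param path Path to an mmCIF (`.cif`) or legacy PDB (`.pdb`/`.ent`) file.
#' @param model Model number to extract (default 1).
#' @param pdb_id Label for the structure; defaults to the file stem.
#' @return A [ribosome_structure()].
#' @export
read_structure <- function(path, model = 1L, pdb_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "riboframe_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  format <- guess_format(path, lines)
  lines <- if (format == "cif") {
    cif_select_model(lines, model, path)
  } else {
    pdb_select_model(lines, model, path)
  }
  tmp <- tempfile(fileext = if (format == "cif") ".cif" else ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(tmp) else bio3d::read.pdb(tmp)
    ),
    error = function(e) {
      abort(sprintf("%s: unparseable %s file (%s)", path,
        if (format == "cif") "_atom_site block of mmCIF" else "ATOM records of PDB",
        conditionMessage(e)), class = "riboframe_format_error")
    }
  )
  at <- parsed$atom
  meta <- extract_header_meta(lines, format)
  if (is.null(pdb_id)) pdb_id <- sub("\\.[^.]+$", "", basename(path))
  ribosome_structure(
    tibble(
      chain = as.character(at$chain),
      resno = as.integer(at$resno),
      insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
      resid = as.character(at$resid),
      elety = as.character(at$elety),
      x = at$x, y = at$y, z = at$z
    ),
    pdb_id = pdb_id,
    resolution = meta$resolution,
    method = meta$method,
    model = model
  )
}

#' Write a structure as minimal mmCIF
#'
#' Emits a single-datablock mmCIF with the `_atom_site` loop (plus resolution
#' and method tags) that [read_structure()] round-trips. Used by the synthetic
#' generators so that every fixture passes through the same file interface as
#' deposited structures.
#'
#' @param s A [ribosome_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(s, path) {
  stopifnot(inherits(s, "ribosome_structure"))
  a <- s$atoms
  elem <- substr(gsub("[^A-Za-z].*$", "", a$elety), 1, 1)
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", s$pdb_id)),
    paste0("_entry.id ", s$pdb_id),
    if (!is.na(s$resolution)) sprintf("_reflns.d_resolution_high %.3f", s$resolution),
    sprintf("_exptl.method '%s'", switch(s$method,
      xray = "X-RAY DIFFRACTION", cryoem = "ELECTRON MICROSCOPY", "OTHER")),
    "loop_",
    # canonical RCSB atom_site field order; bio3d's reader relies on it
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s %d",
    seq_len(nrow(a)), elem, a$elety, a$resid, a$chain, a$resno,
    ifelse(a$insert == "", "?", a$insert),
    a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety, s$model
  )
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

# ---- chain identification ---------------------------------------------------

chain_table <- function(s) {
  s$atoms |>
    distinct(.data$chain, .data$resno, .data$insert, .data$resid) |>
    group_by(.data$chain) |>
    summarise(
      n_res = n(),
      frac_nuc = mean(.data$resid %in% NUCLEOTIDE_RESIDUES),
      .groups = "drop"
    )
}

#' Identify 16S, 23S, mRNA and tRNA chains
#'
#' Heuristic assignment by RNA chain length: 16S is the longest RNA chain of
#' 1400-1700 residues, 23S (optional) 2700-3100, tRNAs 55-110, and mRNA a
#' short RNA chain (< 200 residues, not tRNA-sized) near the 16S decoding
#' region. Explicit `hints` override every heuristic.
#'
#' @param s A [ribosome_structure()].
#' @param hints Optional named list with any of `rrna16S`, `rrna23S`, `mrna`,
#'   `trnas` (character vector of chain ids), `numbering_offset_16S` (integer
#'   added to E. coli numbering to obtain file numbering).
#' @return A `chain_map` list: `rrna16S`, `rrna23S` (`NA` if absent), `mrna`,
#'   `trnas` (tibble of `chain`, `site`), `numbering_offset_16S`.
#' @export
identify_chains <- function(s, hints = NULL) {
  stopifnot(inherits(s, "ribosome_structure"))
  hints <- hints %||% list()
  ct <- chain_table(s)
  rna <- ct |> filter(.data$frac_nuc >= 0.5, .data$n_res >= 2)
  if (nrow(rna) < 2 && is.null(hints$mrna)) {
    abort("structure does not contain at least two nucleic-acid chains",
      class = "riboframe_chain_error")
  }
  check_exists <- function(id, role) {
    if (!is.null(id) && !is.na(id) && !id %in% ct$chain) {
      abort(sprintf("hinted %s chain '%s' is not present in the structure", role, id),
        class = "riboframe_chain_error")
    }
  }
  pick_longest <- function(cand, role, required) {
    if (nrow(cand) == 0) {
      if (required) {
        abort(sprintf("no candidate chain for %s (lengths seen: %s); supply hints", role,
          paste(sort(rna$n_res, decreasing = TRUE), collapse = ", ")),
          class = "riboframe_chain_error")
      }
      return(NA_character_)
    }
    best <- cand |> arrange(desc(.data$n_res))
    if (nrow(best) > 1 && best$n_res[1] == best$n_res[2]) {
      abort(sprintf("ambiguous %s candidates: %s; supply hints", role,
        paste(best$chain, collapse = ", ")), class = "riboframe_chain_error")
    }
    best$chain[1]
  }

  r16 <- hints$rrna16S %||%
    pick_longest(rna |> filter(.data$n_res >= 1400, .data$n_res <= 1700), "16S rRNA", TRUE)
  check_exists(hints$rrna16S, "16S rRNA")
  r23 <- hints$rrna23S %||%
    pick_longest(rna |> filter(.data$n_res >= 2700, .data$n_res <= 3100), "23S rRNA", FALSE)
  check_exists(hints$rrna23S, "23S rRNA")

  trna_cand <- rna |> filter(.data$n_res >= 55, .data$n_res <= 110,
    !.data$chain %in% c(r16, r23))
  trnas <- hints$trnas %||% trna_cand$chain
  for (tc in trnas) check_exists(tc, "tRNA")

  mrna <- hints$mrna
  check_exists(mrna, "mRNA")
  if (is.null(mrna)) {
    cand <- rna |> filter(.data$n_res < 200, !.data$chain %in% c(r16, r23, trnas))
    if (nrow(cand) == 0) {
      abort("no mRNA candidate chain (< 200 residues); supply hints",
        class = "riboframe_chain_error")
    }
    if (nrow(cand) > 1) {
      # disambiguate by proximity to the 16S decoding region (around A1503)
      off <- hints$numbering_offset_16S %||% 0L
      anchor <- s$atoms |> filter(.data$chain == r16,
        .data$resno >= 1490 + off, .data$resno <= 1510 + off)
      if (nrow(anchor) > 0) {
        dmin <- vapply(cand$chain, function(ch) {
          xyz <- s$atoms |> filter(.data$chain == ch)
          min(sqrt(outer(xyz$x, anchor$x, "-")^2 +
            outer(xyz$y, anchor$y, "-")^2 +
            outer(xyz$z, anchor$z, "-")^2))
        }, numeric(1))
        near <- cand$chain[dmin <= 30]
        if (length(near) == 1) {
          cand <- cand |> filter(.data$chain == near)
        }
      }
      if (nrow(cand) > 1) {
        abort(paste0("ambiguous mRNA candidates: ",
          paste(cand$chain, collapse = ", "), "; supply hints"),
          class = "riboframe_chain_error")
      }
    }
    mrna <- cand$chain[1]
  }
  if (identical(r16, mrna)) {
    abort("16S rRNA and mRNA cannot be the same chain", class = "riboframe_chain_error")
  }
  structure(
    list(
      rrna16S = r16,
      rrna23S = r23,
      mrna = mrna,
      trnas = tibble(chain = as.character(trnas),
        site = rep("unknown", length(trnas))),
      numbering_offset_16S = as.integer(hints$numbering_offset_16S %||% 0L)
    ),
    class = "chain_map"
  )
}

# ---- mRNA register ----------------------------------------------------------

WC_EDGE_ATOMS <- list(
  purine = c("N1", "O6", "N6", "N2"),
  pyrimidine = c("N3", "O2", "O4", "N4")
)

wc_edge_xyz <- function(s, chain_id, resno) {
  at <- atoms_of_residue(s, chain_id, resno)
  if (nrow(at) == 0) return(NULL)
  cls <- base_class(at$resid[1])
  if (cls == "unknown") cls <- "purine"
  sel <- at[at$elety %in% WC_EDGE_ATOMS[[cls]], c("x", "y", "z"), drop = FALSE]
  if (nrow(sel) == 0) return(NULL)
  as.matrix(sel)
}

min_cross_dist <- function(a, b) {
  if (is.null(a) || is.null(b)) return(Inf)
  min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2))
}

new_register <- function(chain, p_start, direction, resolvable) {
  structure(
    list(
      chain = chain,
      p_codon_start = as.integer(p_start),
      direction = as.integer(direction),
      resolvable_range = resolvable
    ),
    class = "mrna_register"
  )
}

#' Map an mRNA register-convention position to a residue number
#'
#' Position +1 is the first base of the P-site codon; there is no position 0,
#' and negative positions count 5' from the codon.
#'
#' @param reg An `mrna_register` from [locate_p_codon()].
#' @param pos Integer vector of nonzero positions.
#' @return Integer residue numbers on the mRNA chain.
#' @export
register_residue <- function(reg, pos) {
  stopifnot(inherits(reg, "mrna_register"), all(pos != 0))
  delta <- ifelse(pos > 0, pos - 1L, pos)
  as.integer(reg$p_codon_start + delta * reg$direction)
}

#' @rdname register_residue
#' @param resno Integer vector of residue numbers.
#' @export
register_position <- function(reg, resno) {
  stopifnot(inherits(reg, "mrna_register"))
  delta <- (resno - reg$p_codon_start) * reg$direction
  as.integer(ifelse(delta >= 0, delta + 1L, delta))
}

#' Locate the P-site codon and build the mRNA register
#'
#' The P codon is the mRNA triplet whose three bases each make a
#' Watson-Crick-edge contact within `pairing_cutoff` of the corresponding
#' anticodon base (residues 34-36, antiparallel) of a tRNA. When several
#' tRNA/triplet combinations qualify, the codon nearest the mRNA 5' end is
#' taken as the P codon (and that tRNA labelled P). An explicit
#' `p_codon_start` short-circuits detection.
#'
#' @param s A [ribosome_structure()].
#' @param cm A chain map from [identify_chains()].
#' @param pairing_cutoff Heavy-atom distance cutoff in angstrom (default 3.5).
#' @param p_codon_start Optional explicit residue number of mRNA position +1.
#' @param direction 5'-to-3' residue numbering increment, +1 (default) or -1.
#' @return An `mrna_register`.
#' @export
locate_p_codon <- function(s, cm, pairing_cutoff = 3.5, p_codon_start = NULL,
                           direction = 1L) {
  stopifnot(inherits(s, "ribosome_structure"))
  mres <- chain_residues(s, cm$mrna) |> filter(.data$insert == "")
  if (nrow(mres) < 3) {
    abort("mRNA chain has fewer than 3 residues", class = "riboframe_register_error")
  }
  if (!is.null(p_codon_start)) {
    reg <- new_register(cm$mrna, p_codon_start, direction,
      resolvable_from(mres$resno, p_codon_start, direction))
    return(reg)
  }
  if (nrow(cm$trnas) == 0) {
    abort("no tRNA chain available to anchor the P codon; supply p_codon_start",
      class = "riboframe_register_error")
  }
  resnos <- sort(mres$resno)
  best <- NULL
  for (tch in cm$trnas$chain) {
    ac <- lapply(c(34L, 35L, 36L), function(r) wc_edge_xyz(s, tch, r))
    if (any(vapply(ac, is.null, logical(1)))) next
    for (i in seq_len(length(resnos) - 2)) {
      trip <- resnos[i:(i + 2)]
      if (trip[3] - trip[1] != 2L) next # require consecutive numbering
      # antiparallel pairing: codon base 1 pairs anticodon 36, base 3 pairs 34
      d <- vapply(1:3, function(k) {
        min_cross_dist(wc_edge_xyz(s, cm$mrna, trip[k]), ac[[4 - k]])
      }, numeric(1))
      if (all(d <= pairing_cutoff)) {
        cand <- list(trna = tch, start = trip[1], score = sum(d))
        if (is.null(best) || cand$start < best$start ||
          (cand$start == best$start && cand$score < best$score)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "no mRNA triplet pairs with a tRNA anticodon within %.1f A; register unresolved",
      pairing_cutoff), class = "riboframe_register_error")
  }
  reg <- new_register(cm$mrna, best$start, 1L,
    resolvable_from(resnos, best$start, 1L))
  attr(reg, "p_trna") <- best$trna
  reg
}

resolvable_from <- function(resnos, p_start, direction) {
  delta <- (resnos - p_start) * direction
  pos <- ifelse(delta >= 0, delta + 1L, delta)
  c(min(pos), max(pos))
}

#' @export
print.mrna_register <- function(x, ...) {
  cat(sprintf(
    "<mrna_register> chain %s: +1 at residue %d, direction %+d, positions %d..%d\n",
    x$chain, x$p_codon_start, x$direction,
    x$resolvable_range[1], x$resolvable_range[2]
  ))
  invisible(x)
}

#' Download an mmCIF file by PDB accession
#'
#' Convenience fetcher with a configurable mirror URL template; results are
#' cached in `dir` and never re-downloaded. Not used by any test or by the
#' survey pipeline unless a structure file is absent.
#'
#' @param pdb_id 4-character PDB accession.
#' @param dir Cache directory.
#' @param template URL template with `%s` for the lowercase accession.
#' @return Path to the cached file.
#' @export
fetch_structure <- function(pdb_id, dir = ".",
                            template = "https://files.rcsb.org/download/%s.cif") {
  dest <- file.path(dir, paste0(tolower(pdb_id), ".cif"))
  if (!file.exists(dest)) {
    utils::download.file(sprintf(template, tolower(pdb_id)), dest, quiet = TRUE)
  }
  dest
}
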