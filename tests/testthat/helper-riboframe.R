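# Shared fixtures built in code: registers/chain maps for generator scenes, a
# one-call scene classifier, and an independent codon-table translator used
# as the oracle for fs_products().

scene_register <- function(p_start = 11L) {
  structure(
    list(chain = "m", p_codon_start = p_start, direction = 1L,
      resolvable_range = c(-4L, 4L)),
    class = "mrna_register"
  )
}

scene_chain_map <- function() {
  list(rrna16S = "a", rrna23S = NA_character_, mrna = "m",
    trnas = tibble::tibble(chain = character(), site = character()),
    numbering_offset_16S = 0L)
}

# classify a make_contact_scene() output end to end
classify_scene <- function(sc, thresholds = contact_thresholds()) {
  s <- sc$structure
  g <- mrna_base_geometries(s, scene_chain_map(), scene_register(sc$p_codon_start),
    c(-4:-1, 1:4))
  q <- tryCatch(base_geometry(s, "a", 1503L), error = function(e) NULL)
  classify_contact(q, g, thresholds)
}

# chain map for make_rotated_subunit() output (no mRNA in those fixtures)
subunit_chain_map <- function() {
  list(rrna16S = "a", rrna23S = "A", mrna = "m",
    trnas = tibble::tibble(chain = character(), site = character()),
    numbering_offset_16S = 0L)
}

apply_rigid <- function(s, R, t) {
  a <- s$atoms
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
  a$x <- xyz[, 1]
  a$y <- xyz[, 2]
  a$z <- xyz[, 3]
  ribosome_structure(a, pdb_id = s$pdb_id, resolution = s$resolution,
    method = s$method)
}

# independent brute-force translator (standard code), codon by codon
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons <- c(codons, paste0(b1, b2, b3))
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  dna <- chartr("Uu", "TT", toupper(dna))
  n <- nchar(dna) - nchar(dna) %% 3
  if (n == 0) return("")
  out <- character(0)
  for (i in seq(1, n, 3)) {
    aa <- CODON_TABLE[[substr(dna, i, i + 2)]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# record-level synthetic stand-in for aggregation tests
make_record <- function(pdb_id, state, call, partners = "",
                        confidence = "pass", fail_reason = "") {
  tibble::tibble(
    pdb_id = pdb_id, confidence = confidence, fail_reason = fail_reason,
    state = state, body_angle = 2, head_angle = 2,
    body_sign = "unknown", head_sign = "unknown",
    fit_rmsd_body = 0.1, fit_rmsd_head = 0.1,
    call = call, partners = partners,
    d1 = NA_real_, d2 = NA_real_, alpha1 = NA_real_, alpha2 = NA_real_,
    min_distance = 3.4, contact_flags = "",
    c1397_call = NA_character_, c1397_partners = NA_character_,
    resolution = 3.0, method = "cryoem", config_hash = "h"
  )
}

as_records <- function(df) {
  class(df) <- c("survey_records", class(df))
  df
}
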