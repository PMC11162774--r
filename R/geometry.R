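# Base-centroid / base-plane geometry and the intercalated | stacked |
# retracted classifier for a query base (A1503, optionally C1397) against the
# mRNA. The screen works off three quantities per candidate mRNA base:
#   d     centroid-centroid distance
#   alpha acute angle between the two base planes
#   omega acute angle between the centroid-centroid vector and the query
#         base normal (face-on stacking requires a small omega; edge-on
#         contacts have omega near 90 degrees)

#' Default geometric thresholds for contact classification
#'
#' Standard pi-stacking geometry ranges. Every survey output records the
#' threshold set used, so any count is reproducible from the report alone.
#'
#' @param d_stack Maximum centroid distance for a stacking partner (angstrom).
#' @param alpha_max Maximum interplanar angle (degrees).
#' @param omega_max Maximum angle between the centroid-centroid vector and the
#'   query base normal (degrees); enforces face-on rather than edge contact.
#' @param d_retract Distance beyond which the query is retracted (angstrom).
#' @param tie_tol Distance tolerance for the deterministic partner tie-break
#'   (angstrom; ties resolve toward the more 5' position).
#' @return Named list of thresholds.
#' @export
contact_thresholds <- function(d_stack = 4.5, alpha_max = 30, omega_max = 40,
                               d_retract = 6.0, tie_tol = 0.01) {
  stopifnot(d_stack > 0, d_retract >= d_stack, alpha_max > 0, omega_max > 0)
  list(d_stack = d_stack, alpha_max = alpha_max, omega_max = omega_max,
    d_retract = d_retract, tie_tol = tie_tol)
}

#' Compute the centroid and least-squares plane of a nucleobase
#'
#' The centroid is the unweighted mean of the canonical ring atoms present
#' (purine N1,C2,N3,C4,C5,C6,N7,C8,N9; pyrimidine N1..C6); the normal is the
#' smallest-variance axis of the ring-atom scatter. The normal sign is chosen
#' to point toward the 5' neighbour centroid when one is supplied, otherwise
#' it is arbitrary but recorded.
#'
#' @param s A [ribosome_structure()].
#' @param chain,resno,insert Residue identity.
#' @param neighbor_5p Optional centroid (3-vector) of the 5' neighbour used to
#'   fix the normal sign.
#' @return A `base_geometry` object (`residue`, `base_type`, `centroid`,
#'   `normal`, `ring_atom_count`, `normal_anchored`).
#' @export
base_geometry <- function(s, chain, resno, insert = "", neighbor_5p = NULL) {
  at <- atoms_of_residue(s, chain, resno, insert)
  if (nrow(at) == 0) {
    abort(sprintf("residue %s/%d%s not found", chain, resno, insert),
      class = "riboframe_geometry_error")
  }
  resid <- at$resid[1]
  ring <- at[at$elety %in% ring_atoms_for(resid), , drop = FALSE]
  if (nrow(ring) < 5) {
    abort(sprintf("residue %s/%d (%s) has %d ring atoms (< 5); geometry unresolved",
      chain, resno, resid, nrow(ring)), class = "riboframe_geometry_error")
  }
  xyz <- as.matrix(ring[, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3]
  anchored <- FALSE
  if (!is.null(neighbor_5p)) {
    toward <- neighbor_5p - centroid
    if (sqrt(sum(toward^2)) > 1e-6 && sum(normal * toward) < 0) normal <- -normal
    anchored <- TRUE
  }
  structure(
    list(
      residue = list(chain = chain, resno = as.integer(resno), insert = insert,
        resid = resid),
      base_type = base_class(resid),
      centroid = centroid,
      normal = unit(normal),
      ring_atom_count = nrow(ring),
      normal_anchored = anchored
    ),
    class = "base_geometry"
  )
}

#' @export
print.base_geometry <- function(x, ...) {
  cat(sprintf("<base_geometry> %s/%d %s (%s, %d ring atoms) centroid (%.2f, %.2f, %.2f)\n",
    x$residue$chain, x$residue$resno, x$residue$resid, x$base_type,
    x$ring_atom_count, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# register positions skip 0; map to a gap-free index so adjacency is |diff| == 1
position_index <- function(pos) ifelse(pos > 0, pos, pos + 1L)

#' Base geometries of mRNA positions
#'
#' Convenience wrapper computing [base_geometry()] for a window of
#' register-convention mRNA positions; unresolvable positions (missing residue or
#' fewer than 5 ring atoms) yield a `NULL` geometry rather than an error.
#'
#' @param s A [ribosome_structure()].
#' @param cm Chain map from [identify_chains()].
#' @param reg Register from [locate_p_codon()].
#' @param positions Integer vector of nonzero positions (default -6..+3).
#' @return Tibble with columns `position`, `resno`, `geometry` (list column).
#' @export
mrna_base_geometries <- function(s, cm, reg, positions = c(-6:-1, 1:3)) {
  positions <- positions[positions != 0]
  resnos <- register_residue(reg, positions)
  geoms <- map(seq_along(positions), function(i) {
    prev <- register_residue(reg, if (positions[i] == 1) -1 else positions[i] - 1L)
    nb <- tryCatch(base_geometry(s, cm$mrna, prev)$centroid, error = function(e) NULL)
    tryCatch(base_geometry(s, cm$mrna, resnos[i], neighbor_5p = nb),
      error = function(e) NULL)
  })
  tibble(position = as.integer(positions), resno = resnos, geometry = geoms)
}

format_partners <- function(partners) {
  if (length(partners) == 0) return("")
  paste(partners[order(position_index(partners), decreasing = TRUE)], collapse = "|")
}

#' Classify a query base against the mRNA
#'
#' Codifies the centroid-distance screen plus inspection criteria: an mRNA
#' base is a stacking partner when its centroid lies within `d_stack` of the
#' query centroid, its plane is within `alpha_max` of the query plane, and the
#' centroid-centroid vector is within `omega_max` of the query normal. The
#' call is `intercalated` when two partners sit at consecutive mRNA positions
#' with the query centroid between their planes, `stacked` for a single
#' partner (or two non-consecutive partners, flagged, using the nearer),
#' `retracted` when no base qualifies, and `unresolved` when the required
#' geometry is missing.
#'
#' @param q `base_geometry` of the query base, or `NULL` if unresolvable.
#' @param mrna Tibble from [mrna_base_geometries()] (columns `position`,
#'   `geometry`).
#' @param thresholds From [contact_thresholds()].
#' @return A `contact_call`: `call`, `partners` (register positions),
#'   `centroid_distances`, `plane_angles`, `min_distance`, `flags`,
#'   `thresholds`.
#' @export
classify_contact <- function(q, mrna, thresholds = contact_thresholds()) {
  if (!is_tibble(mrna) || nrow(mrna) == 0) {
    abort("mrna must be a non-empty tibble of base geometries",
      class = "riboframe_validation_error")
  }
  th <- thresholds
  new_call <- function(call, partners = integer(0), d = numeric(0),
                       alpha = numeric(0), min_distance = NA_real_,
                       flags = character(0)) {
    structure(
      list(call = call, partners = as.integer(partners),
        centroid_distances = d, plane_angles = alpha,
        min_distance = min_distance, flags = flags, thresholds = th),
      class = "contact_call"
    )
  }
  valid <- !map_lgl(mrna$geometry, is.null)
  if (is.null(q) || !any(valid)) {
    return(new_call("unresolved", flags = "missing_geometry"))
  }
  g <- mrna[valid, ]
  d <- map_dbl(g$geometry, ~ sqrt(sum((.x$centroid - q$centroid)^2)))
  alpha <- map_dbl(g$geometry, ~ acute_angle(.x$normal, q$normal))
  omega <- map_dbl(g$geometry, ~ acute_angle(.x$centroid - q$centroid, q$normal))
  is_partner <- d <= th$d_stack & alpha <= th$alpha_max & omega <= th$omega_max
  idx <- which(is_partner)
  min_d <- min(d)

  if (length(idx) == 0) {
    return(new_call("retracted", min_distance = min_d))
  }
  # order partners by distance with the deterministic 5'-ward tie-break
  ord <- idx[order(round(d[idx] / th$tie_tol), position_index(g$position[idx]))]
  flags <- character(0)
  if (length(ord) > 2) {
    flags <- c(flags, "multi_partner")
    ord <- ord[1:2]
  }
  if (length(ord) == 2) {
    p <- g$position[ord]
    consecutive <- abs(diff(position_index(p))) == 1
    if (consecutive) {
      n1 <- g$geometry[[ord[1]]]$normal
      n2 <- g$geometry[[ord[2]]]$normal
      if (sum(n1 * n2) < 0) n2 <- -n2
      nbar <- unit(n1 + n2)
      s1 <- sum((q$centroid - g$geometry[[ord[1]]]$centroid) * nbar)
      s2 <- sum((q$centroid - g$geometry[[ord[2]]]$centroid) * nbar)
      if (s1 * s2 < 0) {
        return(new_call("intercalated", partners = p, d = d[ord],
          alpha = alpha[ord], min_distance = min_d, flags = flags))
      }
      flags <- c(flags, "partners_same_side")
    } else {
      flags <- c(flags, "nonconsecutive_partners")
    }
    # stack on the nearer partner
    ord <- ord[1]
  }
  new_call("stacked", partners = g$position[ord], d = d[ord],
    alpha = alpha[ord], min_distance = min_d, flags = flags)
}

#' @export
print.contact_call <- function(x, ...) {
  cat(sprintf("<contact_call> %s%s%s\n", x$call,
    if (length(x$partners)) paste0(" [", format_partners(x$partners), "]") else "",
    if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ","), ")") else ""))
  invisible(x)
}

#' @method tidy contact_call
#' @export
tidy.contact_call <- function(x, ...) {
  tibble(
    call = x$call,
    partners = format_partners(x$partners),
    d1 = if (length(x$centroid_distances) >= 1) x$centroid_distances[1] else NA_real_,
    d2 = if (length(x$centroid_distances) >= 2) x$centroid_distances[2] else NA_real_,
    alpha1 = if (length(x$plane_angles) >= 1) x$plane_angles[1] else NA_real_,
    alpha2 = if (length(x$plane_angles) >= 2) x$plane_angles[2] else NA_real_,
    min_distance = x$min_distance,
    flags = paste(x$flags, collapse = ",")
  )
}
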