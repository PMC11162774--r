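# 30S body and head rotation relative to a classical-state reference.
# Pipeline: (1) superpose the 23S core (fixed frame) of the structure onto the
# reference; (2) the residual rotation of the 16S body atoms gives the body
# (intersubunit) angle via axis-angle decomposition; (3) after aligning body
# frames, the residual rotation of the head atoms gives the head swivel.

#' Default 30S/50S domain definition for rotation measurement
#'
#' Community-standard boundaries: the 30S head is 16S residues 930-1381
#' (E. coli numbering), the body is the remainder of the 16S, and the 23S
#' frame excludes the mobile L1 stalk (2093-2196) and A-site finger
#' (880-898). One atom per residue (phosphorus) keeps the fit robust to base
#' disorder. All ranges are overridable; summary counts depend on them.
#'
#' @param head_16S,body_16S,core_23S Lists of inclusive residue ranges
#'   (length-2 integer vectors), E. coli numbering.
#' @param atom_selector Atom name used per residue.
#' @param forward_axis_body,forward_axis_head Optional unit 3-vectors defining
#'   the forward rotation handedness; when `NULL`, signs are reported as
#'   `"unknown"` and only magnitudes are used (the state windows are
#'   magnitude windows).
#' @param min_atoms Minimum paired atoms per superposition stage.
#' @return A `domain_definition` list.
#' @export
domain_definition <- function(head_16S = list(c(930L, 1381L)),
                              body_16S = list(c(1L, 929L), c(1382L, 1542L)),
                              core_23S = list(c(1L, 879L), c(899L, 2092L),
                                c(2197L, 2879L)),
                              atom_selector = "P",
                              forward_axis_body = NULL,
                              forward_axis_head = NULL,
                              min_atoms = 20L) {
  overlap <- function(a, b) {
    any(vapply(a, function(r1) any(vapply(b, function(r2) {
      r1[1] <= r2[2] && r2[1] <= r1[2]
    }, logical(1))), logical(1)))
  }
  if (overlap(head_16S, body_16S)) {
    abort("head and body residue ranges overlap", class = "riboframe_validation_error")
  }
  structure(
    list(head_16S = head_16S, body_16S = body_16S, core_23S = core_23S,
      atom_selector = atom_selector,
      forward_axis_body = forward_axis_body,
      forward_axis_head = forward_axis_head,
      min_atoms = as.integer(min_atoms)),
    class = "domain_definition"
  )
}

in_ranges <- function(x, ranges) {
  hit <- rep(FALSE, length(x))
  for (r in ranges) hit <- hit | (x >= r[1] & x <= r[2])
  hit
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimising
#' the RMSD of `moving %*% t(R) + t` against `fixed` over paired points.
#'
#' @param moving,fixed n x 3 matrices of paired coordinates, n >= 3.
#' @return List with `R` (3x3), `t` (3-vector), `rmsd` (angstrom), `n`.
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed)) || ncol(moving) != 3) {
    abort("moving and fixed must be equal-size n x 3 matrices",
      class = "riboframe_validation_error")
  }
  n <- nrow(moving)
  if (n < 3) {
    abort("superposition needs at least 3 paired points",
      class = "riboframe_degenerate_fit")
  }
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  mc <- sweep(moving, 2, cm)
  fc <- sweep(fixed, 2, cf)
  sv_m <- svd(mc)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1)) {
    abort("point set is (near-)collinear; superposition is degenerate",
      class = "riboframe_degenerate_fit")
  }
  H <- crossprod(mc, fc) # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- mc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - fc)^2)))
  list(R = R, t = as.numeric(cf - R %*% cm), rmsd = rmsd, n = n)
}

apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$R), 2, fit$t, "+")
}

#' Axis-angle (Euler-Rodrigues) decomposition of a rotation matrix
#'
#' `theta = acos((trace(R) - 1) / 2)` in degrees; the axis comes from the
#' skew-symmetric part, with stable branches near 0 and 180 degrees.
#'
#' @param R 3x3 proper rotation matrix (orthogonal, det = +1 within 1e-6).
#' @return List with `theta` (degrees in `[0, 180]`) and unit `axis`.
#' @export
axis_angle <- function(R) {
  if (!is_rotation_matrix(R)) {
    abort("input is not a proper rotation matrix", class = "riboframe_validation_error")
  }
  ctheta <- (sum(diag(R)) - 1) / 2
  ctheta <- max(-1, min(1, ctheta))
  theta <- acos(ctheta)
  if (theta < 1e-9) {
    return(list(theta = 0, axis = c(0, 0, 1)))
  }
  if (pi - theta < 1e-4) {
    # near 180 degrees the skew part vanishes; recover the axis from
    # B = (R + I) / 2 = axis %o% axis at theta = 180
    B <- (R + diag(3)) / 2
    k <- which.max(diag(B))
    axis <- B[, k] / sqrt(max(B[k, k], .Machine$double.eps))
    return(list(theta = deg(theta), axis = unit(axis)))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  list(theta = deg(theta), axis = unit(axis))
}

#' Rotation matrix from axis and angle (Rodrigues' formula)
#'
#' @param theta Angle in degrees.
#' @param axis Rotation axis (any nonzero 3-vector; normalised internally).
#' @return 3x3 rotation matrix.
#' @export
rotation_from_axis_angle <- function(theta, axis) {
  a <- unit(axis)
  th <- rad(theta)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

domain_points <- function(s, chain_id, ranges, dd, offset = 0L) {
  at <- s$atoms |>
    filter(.data$chain == chain_id, .data$elety == dd$atom_selector,
      .data$insert == "")
  ecoli <- at$resno - offset
  at <- at[in_ranges(ecoli, ranges), , drop = FALSE]
  ecoli <- at$resno - offset
  # one point per residue; duplicates (altloc leftovers) keep the first
  keep <- !duplicated(ecoli)
  m <- as.matrix(at[keep, c("x", "y", "z")])
  rownames(m) <- ecoli[keep]
  m
}

paired <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE],
    n = length(common))
}

sign_label <- function(axis, forward_axis) {
  if (is.null(forward_axis)) return("unknown")
  if (sum(axis * forward_axis) >= 0) "forward" else "reverse"
}

#' Measure 30S body and head rotation against a reference
#'
#' Three-stage procedure on one selected atom per residue: the 23S core of
#' `s` is superposed onto the reference to fix the frame (falling back to the
#' 16S body, flagged, when no 23S chain exists — the body angle is then
#' unmeasurable); the residual 16S-body rotation gives the intersubunit
#' (body) angle; after aligning body frames, the residual head rotation gives
#' the head swivel. Angles are unsigned magnitudes with a sign flag relative
#' to the declared forward axes.
#'
#' @param s,ref [ribosome_structure()] objects; `ref` is the classical-state
#'   reference.
#' @param dd A [domain_definition()].
#' @param cm,cm_ref Chain maps; computed with [identify_chains()] when `NULL`.
#' @return A `rotation_measurement` object.
#' @export
measure_rotations <- function(s, ref, dd = domain_definition(),
                              cm = NULL, cm_ref = NULL) {
  cm <- cm %||% identify_chains(s)
  cm_ref <- cm_ref %||% identify_chains(ref)
  off_s <- cm$numbering_offset_16S
  off_r <- cm_ref$numbering_offset_16S

  body_s <- domain_points(s, cm$rrna16S, dd$body_16S, dd, off_s)
  body_r <- domain_points(ref, cm_ref$rrna16S, dd$body_16S, dd, off_r)
  head_s <- domain_points(s, cm$rrna16S, dd$head_16S, dd, off_s)
  head_r <- domain_points(ref, cm_ref$rrna16S, dd$head_16S, dd, off_r)

  frame <- "core_23S"
  body_measurable <- TRUE
  if (!is.na(cm$rrna23S) && !is.na(cm_ref$rrna23S)) {
    core_s <- domain_points(s, cm$rrna23S, dd$core_23S, dd)
    core_r <- domain_points(ref, cm_ref$rrna23S, dd$core_23S, dd)
  } else {
    frame <- "body_16S"
    body_measurable <- FALSE
    core_s <- body_s
    core_r <- body_r
  }

  stage <- function(a, b, what) {
    pr <- paired(a, b)
    if (pr$n < dd$min_atoms) {
      abort(sprintf("measurement unresolved: only %d paired atoms for %s (need >= %d)",
        pr$n, what, dd$min_atoms), class = "riboframe_measurement_error")
    }
    c(superpose(pr$a, pr$b), list(pair = pr))
  }

  fit_frame <- stage(core_s, core_r, "frame")
  body_s2 <- apply_transform(body_s, fit_frame)
  rownames(body_s2) <- rownames(body_s)
  head_s2 <- apply_transform(head_s, fit_frame)
  rownames(head_s2) <- rownames(head_s)

  if (body_measurable) {
    fit_body <- stage(body_s2, body_r, "body")
    aa_body <- axis_angle(fit_body$R)
    body_angle <- aa_body$theta
    body_axis <- aa_body$axis
    rmsd_body <- fit_body$rmsd
    n_body <- fit_body$n
    head_s3 <- apply_transform(head_s2, fit_body)
    rownames(head_s3) <- rownames(head_s2)
  } else {
    body_angle <- NA_real_
    body_axis <- c(NA_real_, NA_real_, NA_real_)
    rmsd_body <- fit_frame$rmsd
    n_body <- fit_frame$n
    head_s3 <- head_s2
  }

  fit_head <- stage(head_s3, head_r, "head")
  aa_head <- axis_angle(fit_head$R)

  structure(
    list(
      pdb_id = s$pdb_id,
      body_angle = body_angle,
      head_angle = aa_head$theta,
      body_axis = body_axis,
      head_axis = aa_head$axis,
      body_sign = if (body_measurable) sign_label(body_axis, dd$forward_axis_body)
        else "unknown",
      head_sign = sign_label(aa_head$axis, dd$forward_axis_head),
      fit_rmsd_frame = fit_frame$rmsd,
      fit_rmsd_body = rmsd_body,
      fit_rmsd_head = fit_head$rmsd,
      n_atoms = c(frame = fit_frame$n, body = n_body, head = fit_head$n),
      frame = frame
    ),
    class = "rotation_measurement"
  )
}

#' @export
print.rotation_measurement <- function(x, ...) {
  cat(sprintf(
    "<rotation_measurement> %s: body %.2f deg (%s), head %.2f deg (%s), frame = %s\n",
    x$pdb_id, x$body_angle, x$body_sign, x$head_angle, x$head_sign, x$frame))
  invisible(x)
}

#' @method tidy rotation_measurement
#' @export
tidy.rotation_measurement <- function(x, ...) {
  tibble(
    domain = c("body", "head"),
    angle = c(x$body_angle, x$head_angle),
    sign = c(x$body_sign, x$head_sign),
    axis_x = c(x$body_axis[1], x$head_axis[1]),
    axis_y = c(x$body_axis[2], x$head_axis[2]),
    axis_z = c(x$body_axis[3], x$head_axis[3]),
    fit_rmsd = c(x$fit_rmsd_body, x$fit_rmsd_head),
    n_atoms = c(x$n_atoms[["body"]], x$n_atoms[["head"]])
  )
}

#' @method glance rotation_measurement
#' @export
glance.rotation_measurement <- function(x, ...) {
  tibble(
    pdb_id = x$pdb_id, body_angle = x$body_angle, head_angle = x$head_angle,
    body_sign = x$body_sign, head_sign = x$head_sign,
    fit_rmsd_frame = x$fit_rmsd_frame, fit_rmsd_body = x$fit_rmsd_body,
    fit_rmsd_head = x$fit_rmsd_head, frame = x$frame
  )
}

#' Conformational state windows
#'
#' Magnitude windows for state assignment: chimeric-hybrid for 15-21 degrees
#' of 30S head rotation, hybrid for 6-10 degrees of 30S body (intersubunit)
#' rotation, classical (non-rotated) below `classical_body_max` /
#' `classical_head_max`. Precedence: chimeric-hybrid > hybrid > classical;
#' anything outside all windows is `unassigned`.
#'
#' @param chimeric_head,hybrid_body Length-2 inclusive windows (degrees).
#' @param classical_body_max,classical_head_max Upper bounds for the
#'   non-rotated state (degrees).
#' @return A named list of windows.
#' @export
state_windows <- function(chimeric_head = c(15, 21), hybrid_body = c(6, 10),
                          classical_body_max = 3, classical_head_max = 6) {
  list(chimeric_head = chimeric_head, hybrid_body = hybrid_body,
    classical_body_max = classical_body_max,
    classical_head_max = classical_head_max)
}

#' Classify body/head angles into a conformational state
#'
#' Vectorised over angles. `classify_state()` is the object interface for a
#' single [measure_rotations()] result.
#'
#' @param body_angle,head_angle Angles in degrees (`body_angle` may be `NA`
#'   when only the head was measurable).
#' @param body_sign Sign flags; a `"reverse"` body rotation never counts as
#'   hybrid.
#' @param windows From [state_windows()].
#' @return Character vector over
#'   `{classical, hybrid, chimeric_hybrid, unassigned}`.
#' @export
classify_state_angles <- function(body_angle, head_angle,
                                  body_sign = "unknown",
                                  windows = state_windows()) {
  w <- windows
  body_sign <- rep_len(body_sign, length(body_angle))
  chim <- !is.na(head_angle) & head_angle >= w$chimeric_head[1] &
    head_angle <= w$chimeric_head[2]
  hyb <- !is.na(body_angle) & body_angle >= w$hybrid_body[1] &
    body_angle <= w$hybrid_body[2] & body_sign != "reverse"
  cls <- !is.na(body_angle) & !is.na(head_angle) &
    body_angle <= w$classical_body_max & head_angle <= w$classical_head_max
  dplyr::case_when(chim ~ "chimeric_hybrid", hyb ~ "hybrid",
    cls ~ "classical", TRUE ~ "unassigned")
}

#' @rdname classify_state_angles
#' @param m A `rotation_measurement`.
#' @return `classify_state()`: a `state_call` list (`state`, `windows`).
#' @export
classify_state <- function(m, windows = state_windows()) {
  stopifnot(inherits(m, "rotation_measurement"))
  structure(
    list(
      state = classify_state_angles(m$body_angle, m$head_angle, m$body_sign,
        windows),
      windows = windows
    ),
    class = "state_call"
  )
}

#' @export
print.state_call <- function(x, ...) {
  cat(sprintf("<state_call> %s\n", x$state))
  invisible(x)
}
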