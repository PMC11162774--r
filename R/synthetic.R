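# Seeded generators of labelled fixtures. Truth labels are fixed by
# construction (insertion geometry, injected rotation angles), never by the
# classifiers under test, so generator output can serve as an independent
# oracle for every downstream stage.

base_template_atoms <- function(base, chain, resno, origin = c(0, 0, 0),
                                rot = diag(3)) {
  cls <- base_class(base)
  if (cls == "unknown") cls <- "purine"
  tmpl <- RING_TEMPLATES[[cls]]
  xyz <- sweep(tmpl %*% t(rot), 2, origin, "+")
  tibble(
    chain = chain, resno = as.integer(resno), insert = "",
    resid = base, elety = rownames(tmpl),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

rot_z <- function(theta_deg) rotation_from_axis_angle(theta_deg, c(0, 0, 1))
rot_x <- function(theta_deg) rotation_from_axis_angle(theta_deg, c(1, 0, 0))

add_noise <- function(atoms, noise_sd) {
  if (noise_sd <= 0) return(atoms)
  n <- nrow(atoms)
  atoms$x <- atoms$x + rnorm(n, 0, noise_sd)
  atoms$y <- atoms$y + rnorm(n, 0, noise_sd)
  atoms$z <- atoms$z + rnorm(n, 0, noise_sd)
  atoms
}

#' Generate an idealised single-stranded mRNA base stack
#'
#' Bases are built from planar ring templates, stacked along +z (5' at the
#' bottom) with the given helical rise and twist; residues are numbered
#' consecutively so a P-codon-anchored register can be laid over them.
#'
#' @param n_bases Number of bases (>= 2).
#' @param rise Inter-base rise in angstrom (default 3.4).
#' @param twist Helical twist per step in degrees (default 0).
#' @param seed Seed for the coordinate noise; required when `noise_sd > 0`.
#' @param noise_sd Isotropic Gaussian noise per atom coordinate (angstrom).
#' @param bases Residue names, recycled to `n_bases` (default `"U"`).
#' @param chain Chain id (default `"m"`).
#' @param resno_start First residue number.
#' @return A [ribosome_structure()] fragment.
#' @export
make_mrna_stack <- function(n_bases, rise = 3.4, twist = 0, seed = NULL,
                            noise_sd = 0, bases = "U", chain = "m",
                            resno_start = 1L) {
  stopifnot(n_bases >= 2, rise > 0, noise_sd >= 0)
  bases <- rep_len(bases, n_bases)
  atoms <- list_rbind(map(seq_len(n_bases), function(i) {
    base_template_atoms(bases[i], chain, resno_start + i - 1L,
      origin = c(0, 0, (i - 1) * rise), rot = rot_z((i - 1) * twist))
  }))
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    atoms <- add_noise(atoms, noise_sd)
  }
  ribosome_structure(atoms, pdb_id = "mrna_stack", resolution = 2.5,
    method = "cryoem")
}

scene_positions <- function() c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L)

#' Generate a labelled contact scene
#'
#' Builds an 8-base mRNA stack spanning register positions -4..+4 (position +1
#' at residue 11) and inserts an adenine query base in one of three
#' constructions: `intercalated` (midway in a gap widened to twice the rise
#' between `gap_position`), `stacked` (face-on under the 5'-terminal base) or
#' `retracted` (displaced laterally beyond stacking range). After optional
#' noise, construction-label margins (distances at least `margin` beyond the
#' classifier thresholds) are re-checked from raw coordinates and the scene
#' is resampled if violated, so the returned label is guaranteed by geometry,
#' not by the classifier.
#'
#' @param kind `"intercalated"`, `"stacked"` or `"retracted"`.
#' @param rise Stack rise in angstrom.
#' @param gap_position Length-2 vector of consecutive register positions for the
#'   intercalation gap (default `c(-2, -1)`).
#' @param tilt Tilt of the query base plane in degrees (keep below
#'   `alpha_max` minus a margin).
#' @param noise_sd Per-atom Gaussian noise (angstrom).
#' @param seed Integer seed.
#' @param margin Label margin in angstrom beyond the distance thresholds.
#' @param angle_margin Label margin in degrees inside the angular thresholds
#'   for partner bases.
#' @param thresholds Classifier thresholds the margins are measured against.
#' @param query_chain,query_resno Identity given to the query base
#'   (default 16S chain `"a"`, residue 1503).
#' @return List: `structure` (mRNA plus query base), `label`, `partners`
#'   (expected register positions), `p_codon_start` (residue of position +1),
#'   `positions`.
#' @export
make_contact_scene <- function(kind = c("intercalated", "stacked", "retracted"),
                               rise = 3.4, gap_position = c(-2L, -1L),
                               tilt = 0, noise_sd = 0, seed = 1,
                               margin = 0.5, angle_margin = 5,
                               thresholds = contact_thresholds(),
                               query_chain = "a", query_resno = 1503L) {
  kind <- match.arg(kind)
  stopifnot(noise_sd >= 0, margin >= 0)
  positions <- scene_positions()
  p_start <- 11L
  resnos <- ifelse(positions > 0, p_start + positions - 1L, p_start + positions)
  th <- thresholds

  build <- function(attempt) {
    z <- (seq_along(positions) - 1) * rise
    partners <- integer(0)
    if (kind == "intercalated") {
      gp <- gap_position[order(position_index(gap_position))]
      if (diff(position_index(gp)) != 1L) {
        abort("gap_position must be two consecutive register positions",
          class = "riboframe_validation_error")
      }
      i2 <- match(gp[2], positions)
      z[seq_along(z) >= i2] <- z[seq_along(z) >= i2] + rise
      q_origin <- c(0, 0, z[i2 - 1] + rise)
      partners <- gp
    } else if (kind == "stacked") {
      # face-on under the 5'-terminal base (the E-site side, where the query
      # base approaches the mRNA)
      q_origin <- c(0, 0, z[1] - rise)
      partners <- positions[1]
    } else {
      q_origin <- c(th$d_retract + margin + 4, 0, z[4])
    }
    mrna <- list_rbind(map(seq_along(positions), function(i) {
      base_template_atoms("U", "m", resnos[i], origin = c(0, 0, z[i]))
    }))
    query <- base_template_atoms("A", query_chain, query_resno,
      origin = q_origin, rot = rot_x(tilt))
    atoms <- bind_rows(mrna, query)
    if (noise_sd > 0) {
      withr::local_seed(seed + attempt)
      atoms <- add_noise(atoms, noise_sd)
    }
    list(atoms = atoms, partners = partners)
  }

  # raw-coordinate margin check, independent of the classifier
  centroid_of <- function(atoms, ch, rn) {
    a <- atoms[atoms$chain == ch & atoms$resno == rn, ]
    c(mean(a$x), mean(a$y), mean(a$z))
  }
  normal_of <- function(atoms, ch, rn) {
    a <- atoms[atoms$chain == ch & atoms$resno == rn, ]
    xyz <- cbind(a$x, a$y, a$z)
    svd(sweep(xyz, 2, colMeans(xyz)))$v[, 3]
  }
  ang <- function(u, v) {
    180 / pi * acos(min(1, abs(sum(u * v)) /
      sqrt(sum(u^2) * sum(v^2))))
  }
  margins_ok <- function(sc) {
    qc <- centroid_of(sc$atoms, query_chain, query_resno)
    d <- vapply(resnos, function(rn) {
      sqrt(sum((centroid_of(sc$atoms, "m", rn) - qc)^2))
    }, numeric(1))
    if (kind == "retracted") return(all(d >= th$d_retract + margin))
    pidx <- match(sc$partners, positions)
    if (!(all(d[pidx] <= th$d_stack - margin) &&
      all(d[-pidx] >= th$d_stack + margin))) {
      return(FALSE)
    }
    # partner geometry must also clear the angular cutoffs with margin
    qn <- normal_of(sc$atoms, query_chain, query_resno)
    all(vapply(sc$partners, function(p) {
      rn <- resnos[match(p, positions)]
      alpha <- ang(qn, normal_of(sc$atoms, "m", rn))
      omega <- ang(qn, centroid_of(sc$atoms, "m", rn) - qc)
      alpha <= th$alpha_max - angle_margin && omega <= th$omega_max - angle_margin
    }, logical(1)))
  }

  for (attempt in 0:19) {
    sc <- build(attempt)
    if (margins_ok(sc)) {
      s <- ribosome_structure(sc$atoms, pdb_id = paste0("scene_", kind),
        resolution = 3.0, method = "cryoem")
      return(list(structure = s, label = kind, partners = sc$partners,
        p_codon_start = p_start, positions = positions))
    }
  }
  abort("could not generate a scene honouring the label margins at this noise level",
    class = "riboframe_validation_error")
}

uniform_cloud <- function(n, center, half_width = 30) {
  cbind(
    runif(n, center[1] - half_width, center[1] + half_width),
    runif(n, center[2] - half_width, center[2] + half_width),
    runif(n, center[3] - half_width, center[3] + half_width)
  )
}

#' Generate a two-domain 30S stand-in with known injected rotations
#'
#' The reference is a trio of seeded point clouds (one phosphorus-like atom
#' per residue): 16S body, 16S head (residues 930 up) and a 23S core used as
#' the fixed frame. The rotated copy applies the body rotation to the whole
#' 16S about the declared intersubunit axis through the 16S centroid, then
#' the head rotation about the declared head axis through the (rotated) head
#' centroid, then an optional global rigid motion of everything (so the
#' 23S-frame alignment stage does real work), then per-atom Gaussian noise.
#'
#' @param body_angle,head_angle Injected angles in degrees (0-30).
#' @param n_body,n_head,n_core Residues per domain (>= 50).
#' @param noise_sd Per-atom Gaussian noise on the rotated copy (angstrom).
#' @param seed Integer seed for the noise and the global motion.
#' @param body_axis,head_axis Rotation axis orientations.
#' @param global_motion Apply a random global rigid motion to the rotated
#'   copy (default `TRUE`).
#' @param cloud_seed Seed for the domain point clouds themselves. Structures
#'   generated with the same `cloud_seed` share one underlying architecture
#'   (as real ribosomes share a fold) and can be measured against each
#'   other's reference; defaults to `seed`.
#' @return List: `reference`, `rotated` (both [ribosome_structure()]),
#'   `body_angle`, `head_angle`, `body_axis`, `head_axis`.
#' @export
make_rotated_subunit <- function(body_angle, head_angle, n_body = 300L,
                                 n_head = 200L, n_core = 300L, noise_sd = 0,
                                 seed = 1, body_axis = c(0, 0, 1),
                                 head_axis = c(0, 1, 0),
                                 global_motion = TRUE, cloud_seed = seed) {
  stopifnot(body_angle >= 0, body_angle <= 30, head_angle >= 0,
    head_angle <= 30, n_body >= 50, n_head >= 50, n_core >= 50)

  body_res <- seq_len(min(n_body, 929L))
  head_res <- seq(930L, length.out = min(n_head, 452L))
  core_res <- seq_len(min(n_core, 2904L))

  withr::with_seed(cloud_seed, {
    body_xyz <- uniform_cloud(length(body_res), c(0, -35, 0))
    head_xyz <- uniform_cloud(length(head_res), c(0, 35, 0), half_width = 22)
    core_xyz <- uniform_cloud(length(core_res), c(75, 0, 0), half_width = 35)
  })
  withr::local_seed(seed)

  as_atoms <- function(xyz, chain, resno) {
    tibble(chain = chain, resno = as.integer(resno), insert = "", resid = "A",
      elety = "P", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  ref_atoms <- bind_rows(
    as_atoms(body_xyz, "a", body_res),
    as_atoms(head_xyz, "a", head_res),
    as_atoms(core_xyz, "A", core_res)
  )

  rotate_about <- function(xyz, theta, axis, point) {
    R <- rotation_from_axis_angle(theta, axis)
    sweep(sweep(xyz, 2, point) %*% t(R), 2, point, "+")
  }
  ss_center <- colMeans(rbind(body_xyz, head_xyz))
  body_rot <- rotate_about(body_xyz, body_angle, body_axis, ss_center)
  head_rot <- rotate_about(head_xyz, body_angle, body_axis, ss_center)
  head_rot <- rotate_about(head_rot, head_angle, head_axis, colMeans(head_rot))

  rot_atoms <- bind_rows(
    as_atoms(body_rot, "a", body_res),
    as_atoms(head_rot, "a", head_res),
    as_atoms(core_xyz, "A", core_res)
  )
  if (global_motion) {
    Rg <- rotation_from_axis_angle(runif(1, 0, 180), unit(rnorm(3)))
    tg <- runif(3, -20, 20)
    xyz <- as.matrix(rot_atoms[, c("x", "y", "z")]) %*% t(Rg)
    rot_atoms$x <- xyz[, 1] + tg[1]
    rot_atoms$y <- xyz[, 2] + tg[2]
    rot_atoms$z <- xyz[, 3] + tg[3]
  }
  rot_atoms <- add_noise(rot_atoms, noise_sd)

  list(
    reference = ribosome_structure(ref_atoms, pdb_id = "subunit_ref",
      resolution = 3.0, method = "cryoem"),
    rotated = ribosome_structure(rot_atoms, pdb_id = "subunit_rot",
      resolution = 3.0, method = "cryoem"),
    body_angle = body_angle, head_angle = head_angle,
    body_axis = unit(body_axis), head_axis = unit(head_axis)
  )
}

#' Generate a full synthetic ribosome for the survey pipeline
#'
#' Composes a rotated-subunit stand-in (16S chain `a`, 1542 residues; 23S
#' chain `A`, 2904 residues), a contact scene for A1503 against an mRNA
#' 8-mer (chain `m`, position +1 at residue 11), and a 76-residue P-site tRNA
#' (chain `t`) whose anticodon (34-36) is Watson-Crick paired to the +1..+3
#' codon, into one structure with the conformational state and contact kind
#' injected by construction.
#'
#' @param state `"classical"`, `"hybrid"` or `"chimeric_hybrid"`; sets the
#'   injected body/head angles to representative in-window values (0.5/1,
#'   8/2 and 3/18 degrees respectively).
#' @param contact Contact scene kind for A1503.
#' @param seed Integer seed.
#' @param noise_sd Coordinate noise on the rotated subunit clouds.
#' @param resolution Reported resolution stamped into the header.
#' @param drop_mrna_position Optional register position whose ring atoms are
#'   deleted (to exercise the confidence filter).
#' @param gap_position Intercalation gap (forwarded to
#'   [make_contact_scene()]).
#' @return List: `structure`, `reference`, `state`, `contact`, `partners`,
#'   `body_angle`, `head_angle`.
#' @export
make_synthetic_ribosome <- function(state = c("classical", "hybrid",
                                      "chimeric_hybrid"),
                                    contact = c("intercalated", "stacked",
                                      "retracted"),
                                    seed = 1, noise_sd = 0, resolution = 3.0,
                                    drop_mrna_position = NULL,
                                    gap_position = c(-2L, -1L)) {
  state <- match.arg(state)
  contact <- match.arg(contact)
  angles <- switch(state,
    classical = c(0.5, 1),
    hybrid = c(8, 2),
    chimeric_hybrid = c(3, 18)
  )
  # all synthetic ribosomes share one fixed architecture (cloud_seed) so any
  # of them can serve as the rotation reference for any other
  sub <- make_rotated_subunit(angles[1], angles[2],
    n_body = 929L, n_head = 452L, n_core = 2904L,
    noise_sd = noise_sd, seed = seed, global_motion = FALSE, cloud_seed = 1L)
  scene <- make_contact_scene(contact, seed = seed, noise_sd = noise_sd,
    gap_position = gap_position)

  # place the scene well away from the subunit clouds, unrotated
  offset <- c(-120, 0, 0)
  sc_atoms <- scene$structure$atoms
  sc_atoms$x <- sc_atoms$x + offset[1]
  sc_atoms$y <- sc_atoms$y + offset[2]
  sc_atoms$z <- sc_atoms$z + offset[3]
  if (!is.null(drop_mrna_position)) {
    rn <- ifelse(drop_mrna_position > 0, 11L + drop_mrna_position - 1L,
      11L + drop_mrna_position)
    sc_atoms <- sc_atoms[!(sc_atoms$chain == "m" & sc_atoms$resno == rn), ]
  }

  trna <- make_p_trna(sc_atoms, seed = seed)

  # extend the 16S chain with body-range residues 1382..1542 so chain
  # identification sees a 16S-sized chain; residue 1503 exists only as the
  # scene's ring atoms (no phosphorus), so domain fits are unaffected by it
  extend <- function(seed_shift) {
    withr::local_seed(1L + seed_shift) # tied to the shared architecture
    res <- setdiff(1382:1542, 1503L)
    xyz <- uniform_cloud(length(res), c(0, -35, 0))
    tibble(chain = "a", resno = as.integer(res), insert = "", resid = "A",
      elety = "P", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  tail_ref <- extend(7919)
  # rotate the tail rigidly with the body (same axis, angle and pivot as
  # make_rotated_subunit uses for the body cloud)
  tail_rot <- tail_ref
  body_R <- rotation_from_axis_angle(angles[1], c(0, 0, 1))
  ref16 <- sub$reference$atoms[sub$reference$atoms$chain == "a", ]
  ss_center <- c(mean(ref16$x), mean(ref16$y), mean(ref16$z))
  txyz <- sweep(sweep(as.matrix(tail_ref[, c("x", "y", "z")]), 2, ss_center) %*%
    t(body_R), 2, ss_center, "+")
  tail_rot$x <- txyz[, 1]
  tail_rot$y <- txyz[, 2]
  tail_rot$z <- txyz[, 3]

  ref_atoms <- bind_rows(sub$reference$atoms, tail_ref, sc_atoms, trna)
  rot_atoms <- bind_rows(sub$rotated$atoms, tail_rot, sc_atoms, trna)
  # a global rigid motion of the whole rotated structure exercises the
  # 23S-frame alignment stage and the rigid invariance of the contact call
  withr::local_seed(seed + 4243)
  Rg <- rotation_from_axis_angle(runif(1, 0, 180), unit(rnorm(3)))
  tg <- runif(3, -20, 20)
  gxyz <- sweep(as.matrix(rot_atoms[, c("x", "y", "z")]) %*% t(Rg), 2, tg, "+")
  rot_atoms$x <- gxyz[, 1]
  rot_atoms$y <- gxyz[, 2]
  rot_atoms$z <- gxyz[, 3]

  list(
    structure = ribosome_structure(rot_atoms,
      pdb_id = sprintf("synth_%s_%s_%d", state, contact, seed),
      resolution = resolution, method = "cryoem"),
    reference = ribosome_structure(ref_atoms, pdb_id = "synth_ref",
      resolution = 2.5, method = "cryoem"),
    state = state, contact = contact, partners = scene$partners,
    body_angle = angles[1], head_angle = angles[2]
  )
}

# a 76-residue tRNA whose anticodon residues 34-36 pair with the mRNA codon
# at residues 11-13 (antiparallel: 36 pairs +1); the rest of the chain is a
# phosphorus trace placed beside the scene
make_p_trna <- function(scene_atoms, seed = 1, chain = "t") {
  codon_res <- c(11L, 12L, 13L)
  anticodon_res <- c(36L, 35L, 34L)
  paired_atoms <- list_rbind(map(seq_along(codon_res), function(k) {
    m <- scene_atoms[scene_atoms$chain == "m" &
      scene_atoms$resno == codon_res[k], ]
    cen <- c(mean(m$x), mean(m$y), mean(m$z))
    wc <- m[m$elety == wc_atom_for(m$resid[1]), ]
    w <- c(wc$x[1], wc$y[1], wc$z[1])
    u <- w - cen
    u[3] <- 0 # stay in the base plane (scene planes are z-normal)
    u <- unit(u)
    # orient an adenine so its N1 faces back toward the mRNA base
    tmpl <- RING_TEMPLATES$purine
    t_n1 <- tmpl["N1", ]
    cur <- atan2(t_n1[2], t_n1[1])
    want <- atan2(-u[2], -u[1])
    R <- rot_z(deg(want - cur))
    n1_pos <- w + 2.9 * u
    origin <- n1_pos - as.numeric(R %*% t_n1)
    base_template_atoms("A", chain, anticodon_res[k], origin = origin, rot = R)
  }))
  withr::local_seed(seed + 1311)
  rest <- setdiff(1:76, anticodon_res)
  m_all <- scene_atoms[scene_atoms$chain == "m", ]
  beside <- c(mean(m_all$x) + 25, mean(m_all$y), mean(m_all$z))
  xyz <- uniform_cloud(length(rest), beside, half_width = 12)
  bind_rows(
    paired_atoms,
    tibble(chain = chain, resno = as.integer(rest), insert = "", resid = "G",
      elety = "P", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  )
}
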