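# Base centroid/plane computation and the contact classifier.

single_base <- function(base = "G", chain = "m", resno = 1L,
                        origin = c(0, 0, 0), rot = diag(3)) {
  riboframe:::base_template_atoms(base, chain, resno, origin = origin,
    rot = rot)
}

geom_of <- function(atoms, chain = "m", resno = 1L) {
  base_geometry(ribosome_structure(atoms, resolution = 2), chain, resno)
}

test_that("a flat base in the xy-plane has centroid at origin and a z normal", {
  g <- geom_of(single_base("G"))
  expect_lt(sqrt(sum(g$centroid^2)), 1e-9)
  expect_equal(abs(g$normal[3]), 1, tolerance = 1e-9)
  expect_equal(g$base_type, "purine")
  expect_equal(g$ring_atom_count, 9)
  expect_equal(sqrt(sum(g$normal^2)), 1, tolerance = 1e-9)
})

test_that("centroid and normal transform rigidly", {
  R <- rotation_from_axis_angle(37, c(1, 2, 3))
  t <- c(5, -4, 2)
  a0 <- single_base("C")
  xyz <- sweep(as.matrix(a0[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
  a1 <- a0
  a1$x <- xyz[, 1]; a1$y <- xyz[, 2]; a1$z <- xyz[, 3]
  g0 <- geom_of(a0)
  g1 <- geom_of(a1)
  expect_equal(g1$centroid, as.numeric(R %*% g0$centroid + t),
    tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(abs(sum(g1$normal * (R %*% g0$normal))), 1, tolerance = 1e-9)
})

test_that("0.2 A puckering noise tilts the normal by about 5 degrees at most", {
  # plane-fit tilt scales as noise over ring radius: ~4 degrees typical here
  withr::local_seed(42)
  angs <- replicate(50, {
    a <- single_base("A")
    a$z <- a$z + stats::rnorm(nrow(a), 0, 0.2)
    g <- geom_of(a)
    acos(min(1, abs(g$normal[3]))) * 180 / pi
  })
  expect_lt(mean(angs), 5)
  expect_lt(max(angs), 20)
})

test_that("fewer than 5 ring atoms is a geometry-unresolved error", {
  a <- single_base("U")[1:4, ]
  expect_error(geom_of(a), class = "riboframe_geometry_error")
})

# build an mrna geometry table from explicit base placements
mrna_table <- function(placements) {
  atoms <- dplyr::bind_rows(lapply(seq_along(placements), function(i) {
    p <- placements[[i]]
    single_base(p$base %||% "U", "m", i, origin = p$origin,
      rot = p$rot %||% diag(3))
  }))
  s <- ribosome_structure(atoms, resolution = 2)
  tibble::tibble(
    position = vapply(placements, function(p) p$position, integer(1)),
    resno = seq_along(placements),
    geometry = lapply(seq_along(placements), function(i) base_geometry(s, "m", i))
  )
}
`%||%` <- rlang::`%||%`

query_geom <- function(origin, rot = diag(3)) {
  geom_of(single_base("A", "q", 99L, origin = origin, rot = rot), "q", 99L)
}

test_that("a query midway between two parallel bases 6.8 A apart is intercalated", {
  m <- mrna_table(list(
    list(position = -2L, origin = c(0, 0, 0)),
    list(position = -1L, origin = c(0, 0, 6.8)),
    list(position = 1L, origin = c(0, 0, 10.2))
  ))
  cc <- classify_contact(query_geom(c(0, 0, 3.4)), m)
  expect_equal(cc$call, "intercalated")
  expect_setequal(cc$partners, c(-2L, -1L))
  expect_equal(cc$centroid_distances, c(3.4, 3.4), tolerance = 1e-6)
})

test_that("a query 3.4 A over a terminal base with the next base 8 A away stacks", {
  m <- mrna_table(list(
    list(position = 3L, origin = c(0, 0, 0)),
    list(position = 4L, origin = c(0, 0, 8))
  ))
  cc <- classify_contact(query_geom(c(0, 0, 11.4)), m)
  expect_equal(cc$call, "stacked")
  expect_equal(cc$partners, 4L)
})

test_that("a query 20 A from every mRNA base is retracted", {
  m <- mrna_table(list(
    list(position = -1L, origin = c(0, 0, 0)),
    list(position = 1L, origin = c(0, 0, 3.4))
  ))
  cc <- classify_contact(query_geom(c(20, 0, 0)), m)
  expect_equal(cc$call, "retracted")
  expect_length(cc$partners, 0)
})

test_that("edge-on contact at stacking distance is not a partner", {
  # coplanar side-by-side bases: small alpha, but omega ~ 90 degrees
  m <- mrna_table(list(
    list(position = -1L, origin = c(0, 0, 0)),
    list(position = 1L, origin = c(4.2, 0, 0))
  ))
  cc <- classify_contact(query_geom(c(-4.2, 0, 0)), m)
  expect_equal(cc$call, "retracted")
})

test_that("steep interplanar tilt disqualifies an otherwise close base", {
  m <- mrna_table(list(
    list(position = -1L, origin = c(0, 0, 0),
      rot = rotation_from_axis_angle(60, c(1, 0, 0))),
    list(position = 1L, origin = c(0, 0, 20))
  ))
  cc <- classify_contact(query_geom(c(0, 0, 3.4)), m)
  expect_equal(cc$call, "retracted")
})

test_that("two non-consecutive partners stack on the nearer (5'-ward on tie)", {
  m <- mrna_table(list(
    list(position = -3L, origin = c(0, 0, -3.4)),
    list(position = -2L, origin = c(12, 0, 0)),
    list(position = -1L, origin = c(0, 0, 3.4))
  ))
  cc <- classify_contact(query_geom(c(0, 0, 0)), m)
  expect_equal(cc$call, "stacked")
  expect_equal(cc$partners, -3L) # exact tie resolves toward 5'
  expect_true("nonconsecutive_partners" %in% cc$flags)
})

test_that("a same-side partner pair is stacked, not intercalated", {
  m <- mrna_table(list(
    list(position = -2L, origin = c(0, 0, 3.0)),
    list(position = -1L, origin = c(0, 0, 4.4)),
    list(position = 1L, origin = c(0, 0, 20))
  ))
  cc <- classify_contact(query_geom(c(0, 0, 0)), m)
  expect_equal(cc$call, "stacked")
  expect_true("partners_same_side" %in% cc$flags)
})

test_that("missing geometry propagates to an unresolved call", {
  m <- mrna_table(list(
    list(position = -1L, origin = c(0, 0, 0)),
    list(position = 1L, origin = c(0, 0, 3.4))
  ))
  expect_equal(classify_contact(NULL, m)$call, "unresolved")
  m$geometry <- list(NULL, NULL)
  expect_equal(classify_contact(query_geom(c(0, 0, 0)), m)$call, "unresolved")
  expect_error(classify_contact(query_geom(c(0, 0, 0)), tibble::tibble()),
    class = "riboframe_validation_error")
})

test_that("classification is invariant under rigid motions of the scene", {
  withr::local_seed(99)
  for (kind in c("intercalated", "stacked", "retracted")) {
    sc <- make_contact_scene(kind, seed = 17, noise_sd = 0.1, tilt = 8)
    base <- classify_scene(sc)
    for (i in 1:25) {
      R <- rotation_from_axis_angle(stats::runif(1, 0, 180),
        stats::rnorm(3))
      t <- stats::runif(3, -50, 50)
      cc <- classify_scene(list(structure = apply_rigid(sc$structure, R, t),
        p_codon_start = sc$p_codon_start))
      expect_equal(cc$call, base$call)
      expect_equal(cc$partners, base$partners)
      expect_equal(cc$centroid_distances, base$centroid_distances,
        tolerance = 1e-6)
    }
  }
})

test_that("every valid input yields exactly one of the four call values", {
  withr::local_seed(123)
  kinds <- c("intercalated", "stacked", "retracted")
  for (i in 1:30) {
    sc <- make_contact_scene(kinds[(i %% 3) + 1], seed = i, noise_sd = 0.15)
    cc <- classify_scene(sc)
    expect_true(cc$call %in% c("intercalated", "stacked", "retracted",
      "unresolved"))
    expect_length(cc$call, 1)
  }
})

test_that("raising d_stack only moves calls retracted -> stacked -> intercalated", {
  rank_of <- c(retracted = 1, stacked = 2, intercalated = 3)
  # gap scene: query midway between bases 10.4 apart (5.2 A each side)
  m_gap <- mrna_table(list(
    list(position = -2L, origin = c(0, 0, 0)),
    list(position = -1L, origin = c(0, 0, 10.4)),
    list(position = 1L, origin = c(0, 0, 13.8))
  ))
  q_gap <- query_geom(c(0, 0, 5.2))
  # terminal scene: query 5.2 A over the last base
  m_term <- mrna_table(list(
    list(position = 3L, origin = c(0, 0, 0)),
    list(position = 4L, origin = c(0, 0, 3.4))
  ))
  q_term <- query_geom(c(0, 0, 8.6))
  for (scene in list(list(q = q_gap, m = m_gap), list(q = q_term, m = m_term))) {
    prev <- 0
    for (ds in seq(3, 7, by = 0.5)) {
      th <- contact_thresholds(d_stack = ds, d_retract = max(6, ds))
      cc <- classify_contact(scene$q, scene$m, th)
      expect_gte(rank_of[[cc$call]], prev)
      prev <- rank_of[[cc$call]]
    }
  }
})
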