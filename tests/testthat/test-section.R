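test_that("slicing a unit cube at mid-height gives one loop of perimeter 4", {
  cube <- mesh_box()
  loops <- slice_mesh(cube, plane(c(1, 0, 0), 0.5))
  expect_length(loops, 1)
  expect_equal(loop_length(loops[[1]]), 4, tolerance = 1e-9)
  # every loop point lies on the slicing plane
  expect_lt(max(abs(point_plane_distance(loops[[1]]$points,
                                         plane(c(1, 0, 0), 0.5)))), 1e-6)
})

test_that("central icosphere section length approximates the circumference", {
  sph <- mesh_icosphere(subdivisions = 4)
  loops <- slice_mesh(sph, plane(c(0, 0, 1), 0))
  expect_length(loops, 1)
  expect_equal(loop_length(loops[[1]]), 2 * pi, tolerance = 0.01)
})

test_that("a plane through the torus axis yields exactly two loops", {
  tor <- mesh_torus()
  loops <- slice_mesh(tor, plane(c(1, 0, 0), 0))
  expect_length(loops, 2)
})

test_that("plane missing the mesh returns an empty list; open meshes warn", {
  cube <- mesh_box()
  expect_length(slice_mesh(cube, plane(c(1, 0, 0), 5)), 0)
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-5, ])  # drop a side face
  expect_warning(slice_mesh(open_mesh, plane(c(0, 0, 1), 0.25)), "open chain")
})

test_that("on watertight meshes every crossed triangle contributes to a closed loop", {
  fix <- default_fixture()
  for (off in c(0, 3.7, -5.2)) {
    pl <- plane(c(1, 0.05, -0.03), off)
    loops <- slice_mesh(fix$mesh, pl)
    d <- drop(fix$mesh$vertices %*% pl$normal) - pl$offset
    pos <- d > 0 | d == 0
    np <- pos[fix$mesh$faces[, 1]] + pos[fix$mesh$faces[, 2]] + pos[fix$mesh$faces[, 3]]
    n_crossing <- sum(np == 1L | np == 2L)
    n_segments <- sum(vapply(loops, function(l) nrow(l$points) - 1L, integer(1)))
    expect_identical(n_segments, n_crossing)
    for (l in loops) expect_identical(l$points[1, ], l$points[nrow(l$points), ])
  }
})

test_that("body-curve selection picks the loop nearest the body landmarks", {
  fix <- default_fixture()
  lm <- fix$truth$landmarks
  loops <- slice_mesh(fix$mesh, fit_midsagittal_plane(lm))
  expect_gte(length(loops), 2)  # body plus posterior elements
  body <- select_body_curve(loops, lm)
  ctr <- colMeans(body$points[-nrow(body$points), ])
  expect_lt(abs(ctr[2]), 9)  # body loop sits under the endplates, not the laminae
  # single loop and exact-tie cases
  expect_identical(select_body_curve(loops[1], lm), loops[[1]])
  expect_identical(select_body_curve(list(loops[[1]], loops[[1]]), lm), loops[[1]])
  expect_error(select_body_curve(list(), lm), class = "vm_no_section")
})

test_that("planar projection re-aligns, closes, and normalizes orientation", {
  lm <- landmark_set(pev = c(0, -4.8, 6), laminae_intersection = c(0, -24, -6),
                     posterior_rim_midpoint = c(0, -8, -6),
                     up_tip_left = c(12, 0, 8), up_tip_right = c(-12, 0, 8))
  fr <- build_frame(lm)
  sq <- rbind(c(0, 1, 1), c(0, -1, 1), c(0, -1, -1), c(0, 1, -1), c(0, 1, 1))
  sec <- structure(list(points = sq, plane = plane(c(1, 0, 0), 0)),
                   class = "vm_section")
  pc <- to_planar(sec, fr)
  # world (y, z) maps to (ap, si) relative to the origin (0, -8, -6)
  expect_setequal(pc$points[, 1], c(9, 7))
  expect_setequal(pc$points[, 2], c(7, 5))
  n <- nrow(pc$points)
  area2 <- sum(pc$points[, 1] * pc$points[c(2:n, 1), 2] -
                 pc$points[c(2:n, 1), 1] * pc$points[, 2])
  expect_gt(area2, 0)  # counter-clockwise
  # clockwise input is reversed to the same point set
  sec_cw <- structure(list(points = sq[rev(seq_len(5)), ], plane = sec$plane),
                      class = "vm_section")
  pc_cw <- to_planar(sec_cw, fr)
  ord <- function(m) m[order(m[, 1], m[, 2]), ]
  expect_equal(ord(pc_cw$points), ord(pc$points))
  # misaligned curve plane errors
  tilted <- structure(list(points = sq, plane = plane(c(1, 0.1, 0), 0)),
                      class = "vm_section")
  expect_error(to_planar(tilted, fr), class = "vm_misaligned_curve")
})

test_that("rim corners equal the exhaustive support scan on varied curves", {
  # axis-aligned rectangle: corners are the vertices, superior arc the top edge
  rect <- structure(list(points = rbind(c(8, 3), c(-8, 3), c(-8, -3), c(8, -3)),
                         label = "M"), class = "vm_planar_curve")
  sg <- segment_rims(rect)
  expect_identical(unname(sg$corners),
                   c(1L, 2L, 3L, 4L))
  expect_identical(sg$superior, 1:2)
  expect_equal(endplate_depth(arc_points(rect, sg, "superior")), 16)
  # rounded rectangle and random smooth curves vs the brute-force scan
  set.seed(21)
  th <- seq(0, pi / 2, length.out = 12)
  rr <- rbind(cbind(7 + cos(th), 2 + sin(th)),
              cbind(-7 - sin(th), 2 + cos(th)),
              cbind(-7 - cos(th), -2 - sin(th)),
              cbind(7 + sin(th), -2 - cos(th)))
  curves <- c(list(structure(list(points = rr, label = "M"), class = "vm_planar_curve")),
              lapply(1:20, function(i) random_star_curve(seed = 100 + i)))
  dirs <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  names_ <- c("anterosuperior", "posterosuperior", "posteroinferior", "anteroinferior")
  for (pc in curves) {
    sg <- segment_rims(pc)
    for (k in 1:4)
      expect_identical(unname(sg$corners[names_[k]]),
                       oracle_support_corner(pc$points, dirs[k, ]))
    # the four arcs partition the closed curve
    idx <- c(sg$superior[-length(sg$superior)], sg$posterior[-length(sg$posterior)],
             sg$inferior[-length(sg$inferior)], sg$anterior[-length(sg$anterior)])
    expect_setequal(idx, seq_len(nrow(pc$points)))
    expect_identical(anyDuplicated(idx), 0L)
  }
})

test_that("arc depth measures match closed forms and the exhaustive oracle", {
  expect_equal(endplate_depth(rbind(c(0, 0), c(3, 9), c(14.2, 0))), 14.2)
  # semicircular arc of radius 5 on its diameter chord
  th <- seq(0, pi, length.out = 91)
  semi <- cbind(5 * cos(th), 5 * sin(th))
  expect_equal(concave_depth(semi), 5, tolerance = 1e-9)
  # straight arc
  expect_equal(concave_depth(cbind(seq(0, 7, length.out = 15), 0)), 0)
  # densely sampled parabola with apex depth 1.8
  x <- seq(-3, 3, length.out = 2001)
  par_arc <- cbind(x, 1.8 * (1 - (x / 3)^2))
  expect_equal(concave_depth(par_arc), 1.8, tolerance = 1e-6)
  expect_equal(concave_depth(par_arc), oracle_concave_depth(par_arc), tolerance = 1e-12)
  # random wiggly arcs vs the oracle
  set.seed(9)
  for (k in 1:25) {
    x <- sort(runif(40, -5, 5))
    arc <- cbind(x, rnorm(40, 0, 1.5))
    expect_equal(concave_depth(arc), oracle_concave_depth(arc), tolerance = 1e-12)
  }
})

test_that("full pipeline recovers the generator's closed-form truth", {
  fix <- default_fixture()
  rec <- measure_vertebra(fix$mesh, fix$truth$landmarks)
  tr <- fix$truth$true_measurements
  expect_identical(rec$label, c("L", "M", "R"))
  expect_equal(rec$sed_mm[2], 16, tolerance = 0.02 * 16)
  expect_equal(rec$sed_mm[1], 16 * sqrt(0.75), tolerance = 0.02 * 16 * sqrt(0.75))
  expect_equal(rec$iecd_mm[2], 2.4, tolerance = 0.05 * 2.4)
  expect_equal(rec$iecd_mm[1], 1.8, tolerance = 0.05 * 1.8)
  expect_equal(rec$ied_mm, tr$ied_mm, tolerance = 0.02)
})

test_that("measurements are rigid-motion invariant and left-right symmetric", {
  fix <- default_fixture()
  rec <- measure_vertebra(fix$mesh, fix$truth$landmarks)
  expect_equal(rec[rec$label == "L", -1], rec[rec$label == "R", -1],
               tolerance = 1e-6, ignore_attr = TRUE)
  set.seed(31)
  R <- random_rotation(); tr <- c(40, -17, 3)
  rec2 <- measure_vertebra(transform_mesh(fix$mesh, R, tr),
                           transform_landmarks(fix$truth$landmarks, R, tr))
  expect_equal(as.matrix(rec2[, -1]), as.matrix(rec[, -1]), tolerance = 1e-6)
})

test_that("concavity and depth respond monotonically to generator parameters", {
  miecd <- vapply(c(1.8, 2.4, 3.0), function(c0) {
    fix <- generate_vertebra(vertebra_params(c0 = c0))
    measure_vertebra(fix$mesh, fix$truth$landmarks)$iecd_mm[2]
  }, numeric(1))
  expect_true(all(diff(miecd) > 0))
  msed <- vapply(c(14, 16, 18), function(D0) {
    fix <- generate_vertebra(vertebra_params(D0 = D0))
    measure_vertebra(fix$mesh, fix$truth$landmarks)$sed_mm[2]
  }, numeric(1))
  expect_true(all(diff(msed) > 0))
})

test_that("measurement error shrinks with mesh resolution", {
  errs <- vapply(c(1.5, 0.9, 0.5), function(res) {
    fix <- generate_vertebra(vertebra_params(resolution = res))
    rec <- measure_vertebra(fix$mesh, fix$truth$landmarks)
    tr <- fix$truth$true_measurements
    max(abs(as.matrix(rec[, -1]) - as.matrix(tr[, -1])) / as.matrix(tr[, -1]))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], errs[1])
})
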