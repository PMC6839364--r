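# Synthetic rotational kV dose simulator: geometry, linearity, asymmetry.

water_cylinder <- function(radii = c(8, 6), length_cm = 6, organs = list(),
                           voxel = 5) {
  generate_phantom(phantom_spec(radii, length_cm, organs),
                   voxel_size_mm = voxel)
}

test_that("central-axis depth curve is strictly decreasing below the surface", {
  ph <- water_cylinder()
  g <- simulate_rotational_dose(ph$phantom, beam_model(),
                                cbct_protocol("thorax"), angles_deg = 0)
  d <- dim(g$values)
  ix <- ceiling(d[1] / 2); iz <- ceiling(d[3] / 2)
  body <- ph$phantom$labels[ix, , iz] == "tissue"
  depth_curve <- g$values[ix, body, iz]
  expect_gt(length(depth_curve), 5)
  expect_true(all(diff(depth_curve) < 0))
})

test_that("full rotation over a centered cylinder with a symmetric beam is
          rotationally symmetric", {
  ph <- water_cylinder(radii = c(6, 6))
  sym_beam <- beam_model(field_x1_cm = 13.25, field_x2_cm = 13.25,
                         bowtie_strength = 0, heel_strength = 0)
  g <- simulate_rotational_dose(ph$phantom, sym_beam,
                                cbct_protocol("thorax"),
                                angles_deg = seq(-180, 175, by = 5))
  v <- g$values
  d <- dim(v)
  body <- ph$phantom$labels == "tissue"
  # mirror symmetry in x and in y, within discretization tolerance
  for (flip in list(v[d[1]:1, , ], v[, d[2]:1, ])) {
    rel <- abs(v - flip) / pmax(v, max(v) * 1e-6)
    expect_lt(max(rel[body]), 0.05)
  }
})

test_that("pelvis-to-thorax voxel dose ratio equals the mAs ratio", {
  ph <- water_cylinder(organs = list(
    list(organ_id = "liver", center_cm = c(2, 0, 0), radii_cm = c(2, 2, 2))))
  angs <- seq(-180, 150, by = 30)
  b <- beam_model()
  th <- simulate_rotational_dose(ph$phantom, b, cbct_protocol("thorax"),
                                 angs)
  pe <- simulate_rotational_dose(ph$phantom, b, cbct_protocol("pelvis"),
                                 angs)
  nz <- th$values > 0
  expect_true(any(nz))
  expect_equal(range(pe$values[nz] / th$values[nz]), c(4, 4))
  fd <- simulate_rotational_dose(ph$phantom, b, cbct_protocol("fourD"),
                                 angs)
  expect_equal(range(fd$values[nz] / th$values[nz]),
               rep(672 / 360, 2), tolerance = 1e-12)
})

test_that("bowtie and heel produce > 2% lateral and axial asymmetry", {
  ph <- water_cylinder(radii = c(8, 8), length_cm = 12)
  g <- simulate_rotational_dose(ph$phantom, beam_model(),
                                cbct_protocol("fourD"), angles_deg = 0)
  d <- dim(g$values)
  iz <- ceiling(d[3] / 2); ix <- ceiling(d[1] / 2)
  # depth 5 cm below the anterior surface along the beam (y) axis
  body_y <- which(ph$phantom$labels[ix, , iz] == "tissue")
  jy <- body_y[1] + round(50 / g$voxel_size_mm[2])
  lat <- g$values[, jy, iz]
  lat_flip <- rev(lat)
  in_both <- lat > 0 & lat_flip > 0
  expect_gt(max(abs(lat - lat_flip)[in_both] / lat[in_both]), 0.02)
  ax <- g$values[ix, jy, ]
  ax_flip <- rev(ax)
  ok <- ax > 0 & ax_flip > 0
  expect_gt(max(abs(ax - ax_flip)[ok] / ax[ok]), 0.02)
  # disabling the modulators restores symmetry of the axial profile
  g0 <- simulate_rotational_dose(
    ph$phantom, beam_model(bowtie_strength = 0, heel_strength = 0),
    cbct_protocol("fourD"), angles_deg = 0)
  ax0 <- g0$values[ix, jy, ]
  expect_lt(max(abs(ax0 - rev(ax0))[ok] / ax0[ok]), 1e-9)
})

test_that("a posterior couch strictly reduces posterior-entry surface dose", {
  ph <- water_cylinder()
  d <- dim(ph$phantom$labels)
  ix <- ceiling(d[1] / 2); iz <- ceiling(d[3] / 2)
  body_y <- which(ph$phantom$labels[ix, , iz] == "tissue")
  with_couch <- attach_couch(ph$phantom, c(max(body_y) + 1, d[2]))
  b <- beam_model()
  post <- function(phm) {
    g <- simulate_rotational_dose(phm, b, cbct_protocol("thorax"),
                                  angles_deg = 180)
    g$values[ix, max(body_y), iz]  # posterior surface voxel
  }
  expect_lt(post(with_couch), post(ph$phantom))
})

test_that("deeper organs receive lower mean dose than shallower twins", {
  ph <- water_cylinder(radii = c(8, 8), organs = list(
    list(organ_id = "stomach", center_cm = c(0, -4, 0),
         radii_cm = c(1.5, 1.5, 1.5)),
    list(organ_id = "liver", center_cm = c(0, 4, 0),
         radii_cm = c(1.5, 1.5, 1.5))))
  g <- simulate_rotational_dose(ph$phantom, beam_model(),
                                cbct_protocol("thorax"), angles_deg = 0)
  shallow <- mean_organ_dose(g, "stomach", ph$structures)
  deep <- mean_organ_dose(g, "liver", ph$structures)
  expect_gt(shallow, deep)
})

test_that("doubling total mAs doubles organ doses, effective dose and EAR
          through the whole pipeline", {
  ph <- water_cylinder(organs = list(
    list(organ_id = "liver", center_cm = c(2, 0, 0), radii_cm = c(2, 2, 2)),
    list(organ_id = "stomach", center_cm = c(-3, 0, 0),
         radii_cm = c(1.5, 1.5, 1.5))))
  angs <- seq(-180, 140, by = 40)
  b <- beam_model()
  p1 <- cbct_protocol("thorax")
  p2 <- cbct_protocol("thorax", tube_current_mA = 40)  # doubles total mAs
  g1 <- simulate_rotational_dose(ph$phantom, b, p1, angs)
  g2 <- simulate_rotational_dose(ph$phantom, b, p2, angs)
  d1 <- extract_organ_doses(g1, ph$structures)
  d2 <- extract_organ_doses(g2, ph$structures)
  expect_equal(d2$mean_dose_mGy, 2 * d1$mean_dose_mGy, tolerance = 1e-12)
  expect_equal(effective_dose(d2), 2 * effective_dose(d1),
               tolerance = 1e-12)
  e1 <- excess_absolute_risk(d1$mean_dose_mGy[1], "liver", "male")
  e2 <- excess_absolute_risk(d2$mean_dose_mGy[1], "liver", "male")
  expect_equal(e2$ear_per_1e6_py, 2 * e1$ear_per_1e6_py, tolerance = 1e-12)
  # doubling N is the same doubling
  gN <- simulate_rotational_dose(ph$phantom, b,
                                 cbct_protocol("thorax",
                                               n_acquisitions = 2), angs)
  expect_equal(gN$values, 2 * g1$values, tolerance = 1e-12)
})

test_that("effective dose decreases as the body radius grows at fixed
          organ layout", {
  organs <- list(
    list(organ_id = "liver", center_cm = c(2, 0, 0), radii_cm = c(2, 2, 2)),
    list(organ_id = "stomach", center_cm = c(-2.5, 0, 0),
         radii_cm = c(1.5, 1.5, 1.5)))
  angs <- seq(-180, 150, by = 30)
  eff <- vapply(c(6.5, 8, 10), function(r) {
    ph <- water_cylinder(radii = c(1.2 * r, r), organs = organs)
    g <- simulate_rotational_dose(ph$phantom, beam_model(),
                                  cbct_protocol("fourD"), angs)
    effective_dose(extract_organ_doses(g, ph$structures))
  }, numeric(1))
  expect_true(all(diff(eff) < 0))
})

test_that("simulator validates angles", {
  ph <- water_cylinder(radii = c(4, 4), length_cm = 4, voxel = 10)
  b <- beam_model()
  expect_error(simulate_rotational_dose(ph$phantom, b,
                                        cbct_protocol("thorax"),
                                        angles_deg = numeric()),
               "non-empty")
  expect_error(simulate_rotational_dose(ph$phantom, b,
                                        cbct_protocol("thorax"),
                                        angles_deg = 190),
               "-180")
})
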