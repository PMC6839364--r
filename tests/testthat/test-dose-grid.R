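test_that("mean organ dose matches the brute-force voxel loop", {
  g <- random_grid(16, seed = 11)
  m <- random_mask(16, seed = 12)
  oracle <- {
    s <- 0; n <- 0
    for (i in 1:16) for (j in 1:16) for (k in 1:16) {
      if (m[i, j, k]) { s <- s + g$values[i, j, k]; n <- n + 1 }
    }
    s / n
  }
  expect_equal(mean_organ_dose(g, m), oracle, tolerance = 1e-12)
})

test_that("mean organ dose handles uniform and tiny masks", {
  g <- dose_grid(array(5, c(3, 3, 3)))
  expect_equal(mean_organ_dose(g, array(TRUE, c(3, 3, 3))), 5)
  vals <- array(0, c(3, 3, 3)); vals[1:2] <- c(2, 4)
  g2 <- dose_grid(vals)
  m <- array(FALSE, c(3, 3, 3)); m[1:2] <- TRUE
  expect_equal(mean_organ_dose(g2, m), 3)
})

test_that("mean organ dose is permutation-invariant and respects unions", {
  g <- random_grid(8, seed = 3)
  m <- random_mask(8, seed = 4)
  set.seed(5)
  perm <- sample(8^3)
  gp <- dose_grid(array(as.vector(g$values)[perm], c(8, 8, 8)))
  mp <- array(as.vector(m)[perm], c(8, 8, 8))
  expect_equal(mean_organ_dose(gp, mp), mean_organ_dose(g, m))
  # union of disjoint parts = voxel-count-weighted mean
  m2 <- random_mask(8, seed = 6) & !m
  u <- m | m2
  expect_equal(mean_organ_dose(g, u),
               (sum(m) * mean_organ_dose(g, m) +
                  sum(m2) * mean_organ_dose(g, m2)) / sum(u),
               tolerance = 1e-12)
})

test_that("empty or incongruent masks raise errors naming the organ", {
  g <- random_grid(4)
  s <- structure_set(list(lung = array(c(TRUE, rep(FALSE, 63)), c(4, 4, 4))))
  expect_error(mean_organ_dose(g, "heart", s), "heart")
  expect_error(mean_organ_dose(g, array(TRUE, c(2, 2, 2))), "congruent")
  empty <- array(FALSE, c(4, 4, 4))
  expect_error(mean_organ_dose(g, empty), "empty")
  expect_error(structure_set(list(lung = empty)), "empty")
})

test_that("CT-number labelling is piecewise with upper-class ties", {
  ct <- array(c(-1000, -850, -500, -200, 0, 250, 1200, 3000), c(8, 1, 1))
  ph <- label_materials(ct)
  expect_equal(ph$labels[, 1, 1],
               c("air", "lung", "lung", "tissue", "tissue", "bone", "bone",
                 "bone"))
  expect_error(label_materials(ct, thresholds = c(0, -1, 5)), "increasing")
  # densities follow the per-material lookup
  mats <- material_properties()
  expect_equal(ph$mass_density_g_cm3[1, 1, 1],
               mats$density_g_cm3[mats$material == "air"])
})

test_that("couch attachment relabels exactly the slab and rejects overlap", {
  labels <- array("air", c(6, 8, 4))
  labels[2:5, 2:5, ] <- "tissue"
  ph <- material_phantom(labels)
  before <- ph$labels
  out <- attach_couch(ph, c(7, 8))
  expect_equal(sum(out$labels != before), 6 * 2 * 4)
  expect_true(all(out$labels[, 7:8, ] == "tissue"))
  # zero-thickness couch is a no-op
  expect_identical(attach_couch(ph, c(7, 6))$labels, before)
  expect_error(attach_couch(ph, c(5, 6)), "overlaps body")
  expect_error(attach_couch(ph, c(8, 9)), "outside grid")
})

test_that("portable grid I/O is bit-exact and zero grids survive", {
  g <- random_grid(6, seed = 9)
  f <- withr::local_tempfile(fileext = ".grid")
  write_grid(g, f)
  r <- read_grid(f)
  expect_identical(r$values, g$values)
  expect_identical(r$voxel_size_mm, g$voxel_size_mm)
  expect_identical(r$unit, g$unit)
  z <- dose_grid(array(0, c(3, 3, 3)))
  for (dia in c("portable", "rtdose-like")) {
    write_grid(z, f, dia)
    expect_equal(read_grid(f)$values, z$values)
  }
})

test_that("rtdose-like dialect quantizes within the documented bound", {
  g <- random_grid(6, seed = 10)
  M <- max(g$values)
  f <- withr::local_tempfile(fileext = ".grid")
  write_grid(g, f, "rtdose-like")
  r <- read_grid(f)
  scaling <- M / 65535
  expect_lte(max(abs(r$values - g$values)), scaling / 2 + 1e-12)
  expect_lte(max(abs(r$values - g$values)), M / 2^16)
  # explicit quantizer oracle
  q <- round(g$values / scaling) * scaling
  expect_equal(r$values, q, tolerance = 1e-12)
})

test_that("grid reader rejects corrupt headers, shape mismatch and bad scaling", {
  g <- random_grid(4)
  f <- withr::local_tempfile(fileext = ".grid")
  write_grid(g, f)
  lines <- readLines(f)
  writeLines(c("not a grid", lines[-1]), f)
  expect_error(read_grid(f), "magic")
  writeLines(sub("^dims: 4 4 4", "dims: 4 4 5", lines), f)
  expect_error(read_grid(f), "shape mismatch")
  write_grid(g, f, "rtdose-like")
  lines <- readLines(f)
  writeLines(sub("^dose_grid_scaling:.*", "dose_grid_scaling: -1", lines), f)
  expect_error(read_grid(f), "scaling")
})

test_that("structure sets round-trip through the label-volume container", {
  a <- array(FALSE, c(5, 5, 5)); a[1:2, 1:2, 1:2] <- TRUE
  b <- array(FALSE, c(5, 5, 5)); b[4:5, 4:5, 4:5] <- TRUE
  s <- structure_set(list(lung = a, liver = b))
  f <- withr::local_tempfile(fileext = ".labels")
  write_structure_set(s, f)
  r <- read_structure_set(f)
  expect_identical(r$lung, a)
  expect_identical(r$liver, b)
  # overlapping masks cannot be label-encoded
  s2 <- structure_set(list(x = a, y = a))
  expect_error(write_structure_set(s2, f), "disjoint")
})
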