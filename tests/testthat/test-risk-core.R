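test_that("equivalent dose relabels mGy to mSv and scales with w_R", {
  expect_equal(equivalent_dose(14.3, 1.0), 14.3)
  expect_equal(equivalent_dose(0, 1.0), 0)
  expect_equal(equivalent_dose(5.0, 2.0), 10.0)
  expect_error(equivalent_dose(-1), "non-negative")
})

test_that("organ dose tables validate ids, uniqueness and positivity", {
  t <- organ_dose_table(c("Lung", "Adrenal glands"), c(1, 2))
  expect_equal(t$organ_id, c("lung", "adrenals"))
  expect_error(organ_dose_table(c("lung", "lung"), c(1, 2)), "duplicate")
  expect_error(organ_dose_table("lung", -1), "non-negative")
  expect_error(organ_dose_table("eyeball", 1), "unknown organ")
})

test_that("published cohort effective doses are reproduced within 0.1 mSv", {
  for (site in names(ref_effective_dose)) {
    for (mode in names(ref_effective_dose[[site]])) {
      e <- effective_dose(cbct_dose_fixture(site, mode))
      expect_equal(e, ref_effective_dose[[site]][[mode]], tolerance = 0.1 /
                     ref_effective_dose[[site]][[mode]],
                   label = paste(site, mode, "effective dose"))
      expect_lt(abs(e - ref_effective_dose[[site]][[mode]]), 0.1)
    }
  }
})

test_that("effective dose agrees with the naive two-loop oracle", {
  scheme <- icrp103_weights()
  set.seed(42)
  for (rep in 1:5) {
    organs <- sample(organ_registry(), sample(4:20, 1))
    doses <- organ_dose_table(organs, runif(length(organs), 0, 40))
    expect_equal(effective_dose(doses, scheme),
                 effective_dose_oracle(doses, scheme), tolerance = 1e-12)
  }
})

test_that("effective dose is linear, additive and zero on zero doses", {
  doses <- cbct_dose_fixture("lung", "fourD")
  zero <- organ_dose_table(doses$organ_id, rep(0, nrow(doses)))
  expect_equal(effective_dose(zero), 0)
  e1 <- effective_dose(doses)
  doubled <- organ_dose_table(doses$organ_id, 2 * doses$mean_dose_mGy)
  expect_equal(effective_dose(doubled), 2 * e1, tolerance = 1e-12)
  # additivity over a disjoint split sharing one scheme
  i <- seq_len(7)
  a <- organ_dose_table(doses$organ_id[i], doses$mean_dose_mGy[i])
  b <- organ_dose_table(doses$organ_id[-i], doses$mean_dose_mGy[-i])
  expect_equal(effective_dose(a) + effective_dose(b), e1,
               tolerance = 1e-12)
})

test_that("uniform whole-body dose under the full scheme gives E = D", {
  scheme <- icrp103_weights()
  all_organs <- c(names(scheme$explicit_weights), scheme$remainder_organs)
  D <- 12.5
  doses <- organ_dose_table(all_organs, rep(D, length(all_organs)))
  expect_equal(effective_dose(doses, scheme), D, tolerance = 1e-12)
})

test_that("an organ outside the weighting scheme is rejected by name", {
  scheme <- icrp103_weights(explicit_weights = c(lung = 0.12),
                            remainder_organs = c("heart", "spleen"),
                            remainder_divisor = 13)
  doses <- organ_dose_table(c("lung", "liver"), c(1, 1))
  expect_error(effective_dose(doses, scheme), "liver")
})

test_that("missing explicit organs contribute zero (liver cohort thyroid)", {
  doses <- cbct_dose_fixture("liver", "fourD")
  expect_false("thyroid" %in% doses$organ_id)
  e <- effective_dose(doses)
  with_thyroid <- organ_dose_table(c(doses$organ_id, "thyroid"),
                                   c(doses$mean_dose_mGy, 0))
  expect_equal(effective_dose(with_thyroid), e)
})

test_that("EAR reproduces the published per-organ values", {
  # lung-cancer cohort, 4D mode, e = 30, A = 70
  expect_equal(excess_absolute_risk(14.3, "lung", "male")$ear_per_1e6_py,
               7.3, tolerance = 0.15 / 7.3)
  expect_equal(excess_absolute_risk(14.3, "lung", "female")$ear_per_1e6_py,
               10.8, tolerance = 0.15 / 10.8)
  expect_equal(excess_absolute_risk(24.0, "liver", "male")$ear_per_1e6_py,
               9.9, tolerance = 0.15 / 9.9)
  expect_equal(excess_absolute_risk(24.0, "liver", "female")$ear_per_1e6_py,
               4.5, tolerance = 0.15 / 4.5)
  # thyroid resolves through the other-solid fallback; late exposure age
  expect_equal(excess_absolute_risk(18.8, "thyroid", "male",
                                    exposure_age = 60)$ear_per_1e6_py,
               4.0, tolerance = 0.15 / 4.0)
})

test_that("EAR matches the closed-form oracle across the parameter table", {
  p <- beir_parameters()
  cases <- expand.grid(organ = c("lung", "stomach", "liver", "intestine",
                                 "thyroid", "pancreas"),
                       sex = c("male", "female"),
                       e = c(30, 45, 60), stringsAsFactors = FALSE)
  tab <- p$params
  for (k in seq_len(nrow(cases))) {
    org <- cases$organ[k]
    i <- match(org, tab$organ_id)
    if (is.na(i)) i <- match("other_solid", tab$organ_id)
    beta <- if (cases$sex[k] == "male") tab$beta_m[i] else tab$beta_f[i]
    expect_equal(
      excess_absolute_risk(17.7, org, cases$sex[k],
                           cases$e[k], 70)$ear_per_1e6_py,
      ear_oracle(beta, 17.7, tab$gamma[i], cases$e[k], tab$eta[i]),
      tolerance = 1e-12)
  }
})

test_that("EAR limits and input validation behave", {
  expect_equal(excess_absolute_risk(0, "lung", "male")$ear_per_1e6_py, 0)
  # e = 30, A = A0: both modifiers collapse to 1
  expect_equal(excess_absolute_risk(10, "lung", "male", 30,
                                    60)$ear_per_1e6_py,
               100 * 2.3 * 10 / 1000, tolerance = 1e-12)
  expect_error(excess_absolute_risk(10, "lung", "male", 70, 60), ">=")
  expect_error(excess_absolute_risk(-1, "lung", "male"), "non-negative")
})

test_that("EAR is monotone in dose, exposure age and attained age", {
  d <- seq(1, 50, by = 7)
  v <- vapply(d, function(x)
    excess_absolute_risk(x, "lung", "male")$ear_per_1e6_py, numeric(1))
  expect_true(all(diff(v) > 0))
  e <- seq(30, 60, by = 5)
  v <- vapply(e, function(x)
    excess_absolute_risk(20, "lung", "male", x, 70)$ear_per_1e6_py,
    numeric(1))
  expect_true(all(diff(v) < 0))  # gamma < 0
  A <- seq(60, 90, by = 5)
  v <- vapply(A, function(x)
    excess_absolute_risk(20, "lung", "male", 30, x)$ear_per_1e6_py,
    numeric(1))
  expect_true(all(diff(v) > 0))  # eta > 0
})

test_that("EAR time series reproduces the thyroid series and indexes by
          time since exposure", {
  s <- ear_time_series(organ_dose_table("thyroid", 18.8), "male",
                       attained_age = 70, exposure_ages = c(60, 50, 40, 30))
  expect_equal(s$years_since_exposure, c(10, 20, 30, 40))
  expect_equal(s$ear_per_1e6_py, c(4.0, 5.9, 8.7, 12.9), tolerance = 0.02)
})

test_that("stomach EAR is flat in exposure age (gamma near zero)", {
  s <- ear_time_series(organ_dose_table("stomach", 18.0), "male",
                       exposure_ages = 30:60)
  expect_lt(max(s$ear_per_1e6_py) / min(s$ear_per_1e6_py), 1.01)
})

test_that("EAR series shape: one row per organ per exposure age", {
  doses <- cbct_dose_fixture("lung", "fourD")
  s <- ear_time_series(doses, "female", exposure_ages = 40)
  expect_equal(nrow(s), nrow(doses))
  empty <- organ_dose_table(character(), numeric())
  expect_equal(nrow(ear_time_series(empty, "male")), 0)
  expect_error(ear_time_series(doses, "male", exposure_ages = numeric()),
               "non-empty")
  expect_error(ear_time_series(doses, "male", attained_age = 50,
                               exposure_ages = 60), "<=")
})

test_that("weighting scheme config round-trips through YAML", {
  path <- system.file("extdata", "icrp103_weights.yaml",
                      package = "cbctrisk")
  s <- read_weighting_scheme(path)
  expect_equal(sum(s$explicit_weights) + s$remainder_weight, 1.0)
  expect_equal(s$remainder_divisor, 13L)
  expect_length(s$remainder_organs, 13)
  d <- cbct_dose_fixture("lung", "fourD")
  expect_equal(effective_dose(d, s), effective_dose(d, icrp103_weights()))
})
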