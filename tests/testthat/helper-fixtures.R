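# Shared helpers: small random grids/masks and the printed reference
# values used across test files.

random_grid <- function(n = 16L, seed = 1L, voxel = 2.5) {
  set.seed(seed)
  dose_grid(array(stats::runif(n^3, 0, 50), c(n, n, n)),
            voxel_size_mm = rep(voxel, 3))
}

random_mask <- function(n = 16L, seed = 2L, p = 0.3) {
  set.seed(seed)
  m <- array(stats::runif(n^3) < p, c(n, n, n))
  if (!any(m)) m[1] <- TRUE
  m
}

# Published cohort effective doses (mSv) per mode, used as expected values.
ref_effective_dose <- list(
  lung = c(thorax = 3.9, pelvis = 15.7, fourD = 7.3),
  liver = c(thorax = 4.2, pelvis = 16.7, fourD = 7.8)
)

# Independent two-loop oracle for the effective dose: explicit sum over
# tissues and radiation types, remainder as mean over the fixed divisor.
effective_dose_oracle <- function(doses, scheme) {
  radiation <- c(photon = scheme$radiation_weight)
  e <- 0
  for (organ in names(scheme$explicit_weights)) {
    i <- match(organ, doses$organ_id)
    if (is.na(i)) next
    h <- 0
    for (r in names(radiation)) h <- h + radiation[[r]] * doses$mean_dose_mGy[i]
    e <- e + scheme$explicit_weights[[organ]] * h
  }
  rem <- 0
  for (organ in scheme$remainder_organs) {
    i <- match(organ, doses$organ_id)
    if (is.na(i)) next
    h <- 0
    for (r in names(radiation)) h <- h + radiation[[r]] * doses$mean_dose_mGy[i]
    rem <- rem + h
  }
  e + scheme$remainder_weight * rem / scheme$remainder_divisor
}

# Closed-form EAR oracle, independent of the package path.
ear_oracle <- function(beta, dose_mSv, gamma, e, eta, A = 70, A0 = 60) {
  100 * beta * (dose_mSv / 1000) * exp(gamma * (e - 30) / 10) * (A / A0)^eta
}
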