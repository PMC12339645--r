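# Independent brute-force oracles: literal summation loops with their own
# inlined element constants. Deliberately share no code with the package.

oracle_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, Na = 11, Mg = 12, Al = 13,
              Si = 14, P = 15, S = 16, Cl = 17, Ar = 18, K = 19, Ca = 20,
              Ti = 22, Fe = 26, Ba = 56)
oracle_A <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
              Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
              S = 32.06, Cl = 35.45, Ar = 39.95, K = 39.098, Ca = 40.078,
              Ti = 47.867, Fe = 55.845, Ba = 137.327)

# compositions as named percent-by-weight vectors
oracle_comp <- function(material) {
  setNames(material$mass_fraction_percent, material$element)
}

oracle_ean <- function(w, m = 3.3) {
  num <- 0
  den <- 0
  for (el in names(w)) {
    t <- w[[el]] * oracle_Z[[el]] / oracle_A[[el]]
    num <- num + t * oracle_Z[[el]]^m
    den <- den + t
  }
  (num / den)^(1 / m)
}

oracle_zsum <- function(w) {
  s <- 0
  for (el in names(w)) s <- s + w[[el]] * oracle_Z[[el]] / oracle_A[[el]]
  s
}

oracle_water <- c(H = 11.19, O = 88.81)

oracle_red <- function(w, rho, rho_w = 1.0) {
  (rho * oracle_zsum(w) / sum(w)) / (rho_w * oracle_zsum(oracle_water) / sum(oracle_water))
}

oracle_power_sum <- function(w, p) {
  num <- 0
  den <- 0
  for (el in names(w)) {
    t <- w[[el]] * oracle_Z[[el]] / oracle_A[[el]]
    num <- num + t * oracle_Z[[el]]^p
    den <- den + t
  }
  num / den
}

oracle_hu <- function(w, rho, k1, k2, alpha) {
  u <- oracle_red(w, rho) *
    (1 + k1 * oracle_power_sum(w, 1.86) + k2 * oracle_power_sum(w, 3.62)) /
    (1 + k1 * oracle_power_sum(oracle_water, 1.86) +
       k2 * oracle_power_sum(oracle_water, 3.62))
  alpha * 1000 * (u - 1)
}

# enumeration oracle for Dx% of a discrete dose multiset: smallest dose d in
# the sorted list such that at least x% of voxels receive >= d
oracle_dx <- function(doses, x) {
  doses <- sort(doses, decreasing = TRUE)
  n <- length(doses)
  k <- floor(n * x / 100)
  if (k < 1) k <- 1
  doses[k]
}

# helper materials for fit exercises: compositionally diverse, covering the
# lung-to-bone range a calibration phantom spans
bone_like_material <- function() {
  ct_material(data.frame(
    element = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Ca"),
    mass_fraction_percent = c(3.4, 15.5, 4.2, 43.5, 0.1, 0.2, 10.3, 0.3, 22.5)),
    name = "bone-like", mass_density = 1.92)
}

lung_like_material <- function() {
  ct_material(data.frame(
    element = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
    mass_fraction_percent = c(10.3, 10.5, 3.1, 74.9, 0.2, 0.2, 0.3, 0.3, 0.2)),
    name = "lung-like", mass_density = 0.26)
}

adipose_like_material <- function() {
  ct_material(data.frame(
    element = c("H", "C", "N", "O", "Na", "S", "Cl"),
    mass_fraction_percent = c(11.4, 59.8, 0.7, 27.8, 0.1, 0.1, 0.1)),
    name = "adipose-like", mass_density = 0.95)
}

# air is excluded: with alpha > 1 its model CT number would fall below the
# -1000 HU floor a scanner can report, which calibration_points rejects
fit_material_set <- function() {
  list(lung_like_material(), adipose_like_material(), water_material(),
       icrp110_brain_material(), bone_like_material())
}
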