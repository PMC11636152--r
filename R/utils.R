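#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

# Round half away from zero (base round() is banker's rounding; reported
# ratios and percentages follow the conventional half-up rule).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Gaussian FWHM <-> sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# Hertz prefactor A such that F = A * delta^(3/2), with F in pN, delta in nm,
# modulus in Pa and probe radius in nm.  1 Pa = 1e-6 pN/nm^2.
hertz_prefactor <- function(modulus_pa, probe_radius_nm, poisson_ratio = 0.5) {
  stopifnot(modulus_pa > 0, probe_radius_nm > 0)
  (4 / 3) * (modulus_pa * 1e-6 / (1 - poisson_ratio^2)) * sqrt(probe_radius_nm)
}

# Hertz indentation (nm) at force F (pN)
hertz_indentation <- function(force_pN, modulus_pa, probe_radius_nm,
                              poisson_ratio = 0.5) {
  (force_pN / hertz_prefactor(modulus_pa, probe_radius_nm, poisson_ratio))^(2 / 3)
}

# Spring constant N/m -> pN/nm (1 N/m = 1000 pN/nm)
spring_pN_per_nm <- function(spring_constant_N_per_m) {
  spring_constant_N_per_m * 1000
}

# Simple union-find used for label merging and match-graph components
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union_pairs <- function(n, a, b) {
  parent <- uf_new(n)
  for (k in seq_along(a)) {
    ra <- uf_find(parent, a[k])
    rb <- uf_find(parent, b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  # path-compress to roots
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
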