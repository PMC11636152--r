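# Shared fixtures, all generated in code at test time.

# One circular/elliptical pore at the field centre
one_pore_model <- function(d = 200, roundness = 1, orientation = 0,
                           field = 2000, open = TRUE) {
  a <- d / sqrt(roundness); b <- d * sqrt(roundness)
  cell_model(field_size = c(field, field),
             pores = data.frame(id = 1L, x = field / 2, y = field / 2,
                                axis_major = a, axis_minor = b,
                                orientation = orientation, open = open,
                                plate_id = 1L),
             plates = data.frame(id = 1L, x = field / 2, y = field / 2,
                                 radius = field / 2))
}

# A half-plane-like membrane edge: one huge gap whose boundary crosses the
# field almost straight (circle of radius `R` centred far to the right).
edge_model <- function(field_w = 4000, field_h = 2000, R = 1e5) {
  edge_x <- field_w / 2
  cell_model(field_size = c(field_w, field_h),
             gaps = data.frame(id = 1L, x = edge_x + R, y = field_h / 2,
                               axis_major = 2 * R, axis_minor = 2 * R,
                               orientation = 0, open = TRUE,
                               plate_id = NA_integer_))
}

# Synthetic Hertz approach curve on a piezo grid parametrized by
# indentation (independent of render_qi).
make_hertz_curve <- function(E = 750, r = 3950, nu = 0.5, k = 0.01,
                             zc = 500, delta_max = 250, n_contact = 200,
                             n_pre = 60, noise_sd = 0, seed = NULL) {
  A <- fencorr:::hertz_prefactor(E, r, nu)
  k_pn <- k * 1000
  delta <- seq(0, delta_max, length.out = n_contact)
  Fh <- A * delta^1.5
  z_post <- zc - delta - Fh / k_pn
  z_pre <- seq(zc + 200, zc + 1, length.out = n_pre)
  force <- c(rep(0, n_pre), Fh)
  if (noise_sd > 0) {
    force <- force + fencorr:::with_seed(seed, rnorm(length(force), 0, noise_sd))
  }
  force_curve(c(z_pre, z_post), force, k)
}

# Build a qi_map object directly from per-pixel force curves on a shared
# ramp (for oracles that must not depend on render_qi).
manual_qi_map <- function(force_array, z, spring_constant, pixel_size = 30,
                          max_force = NULL) {
  structure(list(piezo_height = z, force = force_array,
                 pixel_size = pixel_size, spring_constant = spring_constant,
                 max_force = max_force %||% max(force_array),
                 meta = list(), truth = NULL),
            class = "qi_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-permutation assignment oracle for small matching instances:
# maximize matched pairs within the gate, then minimize total distance.
brute_force_match <- function(pa, pb, gate) {
  na <- nrow(pa); nb <- nrow(pb)
  d <- outer(seq_len(na), seq_len(nb), function(i, j) {
    sqrt((pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2)
  })
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_card <- -1; best_cost <- Inf
  stopifnot(na <= nb)
  for (p in perms(seq_len(nb))) {
    sel <- p[seq_len(na)]
    ok <- d[cbind(seq_len(na), sel)] <= gate
    card <- sum(ok); cost <- sum(d[cbind(seq_len(na), sel)][ok])
    if (card > best_card || (card == best_card && cost < best_cost - 1e-12)) {
      best_card <- card; best_cost <- cost
      best <- cbind(a = seq_len(na)[ok], b = sel[ok])
    }
  }
  list(pairs = best[order(best[, "a"]), , drop = FALSE],
       cardinality = best_card, cost = best_cost)
}

# Paired wet/dry ground-truth scenario used by matching and dilation tests
wet_dry_scenario <- function(n_plates = 4, pores_per_plate = 500,
                             lambda = 1.34, seed = 11,
                             field = c(42000, 42000),
                             edge_elongation = 1, p_open = 0) {
  wet <- generate_cell_model(field_size = field, n_plates = n_plates,
                             pores_per_plate = pores_per_plate,
                             min_separation = 100, seed = seed)
  dry <- apply_dehydration(wet, dehydration_params(
    lambda_dilation = lambda, edge_fraction = 0.2,
    edge_elongation = edge_elongation, p_open_on_drying = p_open,
    seed = seed + 1))
  list(wet = wet, dry = dry)
}
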