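# Force-curve processing: contact point, topography, Hertz, tomography

test_that("contact point: hard wall, noise robustness, error path", {
  k <- 0.1; k_pn <- 100
  z <- seq(300, 0, length.out = 128)
  f <- k_pn * pmax(100 - z, 0)
  cv <- force_curve(z, f, k)
  dz <- abs(diff(z)[1])
  expect_lt(abs(find_contact_point(cv, force_noise = 1) - 100), dz + 1e-9)

  hits <- vapply(1:40, function(s) {
    fn <- f + fencorr:::with_seed(s, rnorm(length(f), 0, 5))
    cvn <- force_curve(z, fn, k)
    abs(find_contact_point(cvn, force_noise = 5) - 100) <= 3 * dz
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(find_contact_point(force_curve(z, rep(0, 128), k)),
               "no contact")
})

test_that("topography reconstruction matches a brute-force per-pixel scan", {
  # 16 x 16 synthetic map of Hertz curves with varying stiffness + contact
  set.seed(5)
  k <- 0.2; k_pn <- 200
  z <- seq(400, 0, length.out = 96)
  hs <- matrix(runif(256, 120, 220), 16)
  Es <- matrix(10^runif(256, 4.5, 6), 16)
  farr <- array(0, c(16, 16, 96))
  for (i in 1:16) for (j in 1:16) {
    A <- fencorr:::hertz_prefactor(Es[i, j], 20)
    s <- pmax(hs[i, j] - z, 0)
    delta <- fencorr:::solve_indentation(s, A / k_pn)
    farr[i, j, ] <- A * delta^1.5
  }
  qm <- manual_qi_map(farr, z, k)
  topo <- reconstruct_topography(qm, 150)

  # independent exhaustive scan with the same interpolation contract
  oracle <- matrix(NA_real_, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    fv <- farr[i, j, ]
    for (s in seq_along(fv)) {
      if (fv[s] >= 150) {
        if (s == 1) { zf <- z[1] } else if (fv[s - 1] <= 0) {
          zf <- z[s] + (150 - fv[s]) * (z[s + 1] - z[s]) / (fv[s + 1] - fv[s])
        } else {
          zf <- z[s - 1] + (150 - fv[s - 1]) * (z[s] - z[s - 1]) /
            (fv[s] - fv[s - 1])
        }
        oracle[i, j] <- zf + 150 / k_pn
        break
      }
    }
  }
  expect_equal(topo$pixels, oracle, tolerance = 1e-12)

  # per-pixel Hertzian closed form: height(F) = contact - (F/A)^(2/3)
  A11 <- fencorr:::hertz_prefactor(Es[1, 1], 20)
  expect_equal(topo$pixels[1, 1], hs[1, 1] - (150 / A11)^(2 / 3),
               tolerance = 0.5)   # interpolation error < 1 nm by design
  expect_error(reconstruct_topography(qm, 10 * max(farr)), "max_force")
})

test_that("reconstructed height is non-increasing in load force", {
  m <- generate_cell_model(field_size = c(2000, 2000), n_plates = 1,
                           pores_per_plate = 6, diameter_mean = 140,
                           diameter_sd = 20, seed = 21)
  q <- render_qi(m, qi_preset("FA", pixel_size = 20))
  h1 <- reconstruct_topography(q, 70)$pixels
  h2 <- reconstruct_topography(q, 160)$pixels
  h3 <- reconstruct_topography(q, 279)$pixels
  expect_true(all(h2 <= h1 + 1e-9))
  expect_true(all(h3 <= h2 + 1e-9))
})

test_that("deflection correction is exact for a linear-spring sample", {
  k_c <- 0.1; k_c_pn <- 100; k_s_pn <- 50   # sample stiffness 50 pN/nm
  z <- seq(400, 0, length.out = 128)
  h <- 200
  k_eff <- 1 / (1 / k_s_pn + 1 / k_c_pn)
  f <- k_eff * pmax(h - z, 0)
  farr <- array(rep(f, each = 4), c(2, 2, 128))
  qm <- manual_qi_map(farr, z, k_c)
  h1 <- reconstruct_topography(qm, 60)$pixels[1, 1]
  h2 <- reconstruct_topography(qm, 180)$pixels[1, 1]
  expect_equal(h1 - h2, (180 - 60) / k_s_pn, tolerance = 1e-9)
})

test_that("Hertz fit: noiseless recovery, origin, noise, error paths", {
  cv <- make_hertz_curve(E = 750, r = 3950, k = 0.01)
  fit <- fit_hertz(cv, 3950, 0.5, fit_force_cap = 200)
  expect_lt(abs(fit$apparent_modulus - 750) / 750, 0.01)
  # delta = 0 at F = 0: fitted curve passes through the origin
  expect_lt(abs(fit$contact_height - 500), 0.1)
  expect_lt(fit$fit_rms, 1e-3)

  med <- median(vapply(1:64, function(s) {
    cvn <- make_hertz_curve(E = 750, r = 3950, k = 0.01, noise_sd = 5,
                            seed = s)
    fit_hertz(cvn, 3950, 0.5, 200, force_noise = 5)$apparent_modulus
  }, numeric(1)))
  expect_lt(abs(med - 750) / 750, 0.05)

  short <- make_hertz_curve(E = 750, r = 3950, k = 0.01, n_contact = 180)
  expect_error(fit_hertz(short, 3950, 0.5, fit_force_cap = 0.04), "8 post-contact")
})

test_that("elasticity map: uniform CV, 7.2-fold two-region contrast, empty", {
  z <- seq(400, 0, length.out = 96)
  build <- function(E, noise_seed = NULL) {
    A <- fencorr:::hertz_prefactor(E, 3950); k_pn <- 10
    s <- pmax(250 - z, 0)
    delta <- fencorr:::solve_indentation(s, A / k_pn)
    f <- A * delta^1.5
    if (!is.null(noise_seed)) {
      f <- f + fencorr:::with_seed(noise_seed, rnorm(length(f), 0, 2))
    }
    f
  }
  farr <- array(0, c(8, 8, 96))
  for (i in 1:8) for (j in 1:8) farr[i, j, ] <- build(900)
  qm <- manual_qi_map(farr, z, 0.01)
  em <- elasticity_map(qm, c(8, 8), probe_radius = 3950, fit_force_cap = 200)
  expect_true(all(em$ok))
  cv <- sd(em$apparent_modulus_Pa) / mean(em$apparent_modulus_Pa)
  expect_lt(cv, 0.02)

  # live vs GA-fixed scenario: a 7.2-fold modulus contrast is recovered
  farr2 <- farr
  s <- 0
  for (i in 1:8) for (j in 5:8) {
    s <- s + 1
    farr2[i, j, ] <- build(900 * 7.2, noise_seed = s)
  }
  for (i in 1:8) for (j in 1:4) {
    s <- s + 1
    farr2[i, j, ] <- build(900, noise_seed = s)
  }
  qm2 <- manual_qi_map(farr2, z, 0.01)
  em2 <- elasticity_map(qm2, c(8, 8), probe_radius = 3950,
                        fit_force_cap = 200, force_noise = 2)
  ratio <- median(em2$apparent_modulus_Pa[em2$col >= 5]) /
    median(em2$apparent_modulus_Pa[em2$col <= 4])
  expect_lt(abs(ratio - 7.2) / 7.2, 0.05)

  expect_equal(nrow(elasticity_map(qm, c(0, 0), probe_radius = 3950)), 0)
})

test_that("force tomography: rigid sample shows zero change; presets differ", {
  m <- generate_cell_model(field_size = c(2500, 2500), n_plates = 1,
                           pores_per_plate = 10, diameter_mean = 150,
                           diameter_sd = 25, seed = 31)
  rigid <- render_qi(m, afm_params(pixel_size = 20, membrane_modulus = 1e9,
                                   substrate_modulus = 1e9,
                                   rim_compliance = 0, tip_radius = 10))
  ft <- force_tomography(rigid, c(70, 140, 280))
  expect_equal(ft$pct_change, c(0, 0, 0), tolerance = 1e-9)

  ga <- force_tomography(render_qi(m, qi_preset("GA", pixel_size = 20)),
                         c(70, 140, 280))
  fa <- force_tomography(render_qi(m, qi_preset("FA", pixel_size = 20)),
                         c(70, 140, 280))
  expect_lt(abs(ga$pct_change[3]), 10)    # GA: < 10% tip-induced dilation
  expect_gt(fa$pct_change[3], 25)         # FA: > 25%
  # tomographic dilation is monotone in load force
  expect_true(all(diff(ga$mean_d_eq_nm) >= -1e-9))
  expect_true(all(diff(fa$mean_d_eq_nm) >= -1e-9))
  # FA dilates more than GA at every force step
  expect_true(all(fa$pct_change >= ga$pct_change - 1e-9))
})

test_that("qi render errors when max_force is unreachable", {
  m <- one_pore_model(d = 200, field = 1000)
  expect_error(render_qi(m, afm_params(pixel_size = 20, ramp_length = 300,
                                       membrane_modulus = 1e3,
                                       max_force = 500)),
               "unreachable")
})
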