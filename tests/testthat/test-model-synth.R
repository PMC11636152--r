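# Ground-truth generator and dehydration transform

test_that("empty field gives an empty model with full mask area", {
  m <- generate_cell_model(field_size = c(3000, 2000), n_plates = 0,
                           n_gaps = 0, seed = 1)
  expect_s3_class(m, "cell_model")
  expect_equal(nrow(m$pores), 0)
  expect_equal(nrow(m$gaps), 0)
  expect_equal(m$cell_mask_area, 3000 * 2000)
})

test_that("equivalent diameters follow the requested truncated Gaussian", {
  m <- generate_cell_model(field_size = c(50000, 50000), n_plates = 10,
                           pores_per_plate = 500, diameter_mean = 158,
                           diameter_sd = 40, seed = 123)
  d <- sqrt(m$pores$axis_major * m$pores$axis_minor)
  expect_length(d, 5000)
  expect_lt(abs(mean(d) - 158), 3 * 40 / sqrt(5000))
  expect_lt(abs(sd(d) - 40), 0.05 * 40)
  expect_true(all(d > 0))
})

test_that("generator invariants hold: geometry, separation, reproducibility", {
  m <- generate_cell_model(field_size = c(8000, 8000), n_plates = 3,
                           pores_per_plate = 30, seed = 7)
  p <- m$pores
  expect_true(all(p$axis_minor <= p$axis_major))
  expect_true(all(p$axis_minor > 0))
  # roundness within (0, 1]
  expect_true(all(p$axis_minor / p$axis_major > 0 &
                    p$axis_minor / p$axis_major <= 1))
  # pairwise boundary distance > 0 (circumscribed-circle bound)
  dmat <- as.matrix(dist(cbind(p$x, p$y)))
  rads <- outer(p$axis_major, p$axis_major, "+") / 2
  diag(dmat) <- Inf
  expect_true(all(dmat > rads | !is.finite(dmat)))
  # pores inside their plates
  pl <- m$plates[match(p$plate_id, m$plates$id), ]
  expect_true(all(sqrt((p$x - pl$x)^2 + (p$y - pl$y)^2) + p$axis_major / 2 <=
                    pl$radius + 1e-9))
  # identical inputs -> identical model
  m2 <- generate_cell_model(field_size = c(8000, 8000), n_plates = 3,
                            pores_per_plate = 30, seed = 7)
  expect_identical(m, m2)
})

test_that("closed_fraction and crowding limits behave", {
  m <- generate_cell_model(n_plates = 2, pores_per_plate = 10,
                           closed_fraction = 1, seed = 3)
  expect_true(all(!m$pores$open))
  expect_error(
    generate_cell_model(field_size = c(1500, 1500), n_plates = 1,
                        pores_per_plate = 400, seed = 4),
    "density|packing|field")
})

test_that("dehydration with identity parameters is a no-op", {
  m <- generate_cell_model(n_plates = 2, pores_per_plate = 20, seed = 5)
  d <- apply_dehydration(m, dehydration_params(lambda_dilation = 1,
                                               edge_elongation = 1,
                                               p_open_on_drying = 0, seed = 1))
  expect_equal(d$pores, m$pores)
})

test_that("uniform dilation scales open-pore diameters by exactly lambda", {
  m <- generate_cell_model(n_plates = 3, pores_per_plate = 25,
                           closed_fraction = 0.2, seed = 6)
  lam <- 1.34
  d <- apply_dehydration(m, dehydration_params(lambda_dilation = lam,
                                               edge_fraction = 0,
                                               edge_elongation = 1,
                                               p_open_on_drying = 0, seed = 2))
  expect_equal(d$pores$x, m$pores$x)   # centres fixed, count preserved
  expect_equal(d$pores$y, m$pores$y)
  expect_equal(nrow(d$pores), nrow(m$pores))
  open <- m$pores$open
  dw <- sqrt(m$pores$axis_major * m$pores$axis_minor)
  dd <- sqrt(d$pores$axis_major * d$pores$axis_minor)
  expect_equal(dd[open], lam * dw[open], tolerance = 1e-12)
  expect_equal(dd[!open], dw[!open])   # closed pores untouched at p_open = 0
  expect_equal(d$pores$open, m$pores$open)
  # a circular 158 nm pore dilates to 211.7 nm at lambda 1.34
  expect_equal(158 * 1.34, 211.72)
})

test_that("edge elongation stretches radially: roundness / area closed forms", {
  field <- 4000
  # circular pore near the plate rim
  m <- cell_model(field_size = c(field, field),
                  pores = data.frame(id = 1L, x = field / 2 + 900, y = field / 2,
                                     axis_major = 200, axis_minor = 200,
                                     orientation = 0, open = TRUE, plate_id = 1L),
                  plates = data.frame(id = 1L, x = field / 2, y = field / 2,
                                      radius = 1000))
  d <- apply_dehydration(m, dehydration_params(lambda_dilation = 1,
                                               edge_fraction = 0.2,
                                               edge_elongation = 1.3,
                                               p_open_on_drying = 0, seed = 1))
  r_wet <- m$pores$axis_minor / m$pores$axis_major
  r_dry <- d$pores$axis_minor / d$pores$axis_major
  expect_equal(r_dry, r_wet / 1.3, tolerance = 1e-12)
  a_wet <- pi * m$pores$axis_major * m$pores$axis_minor / 4
  a_dry <- pi * d$pores$axis_major * d$pores$axis_minor / 4
  expect_equal(a_dry / a_wet, 1.3, tolerance = 1e-12)
  # rasterized pixel-count oracle for the same area ratio
  px_wet <- sum(1 - rasterize_indicator(m, 5))
  px_dry <- sum(1 - rasterize_indicator(d, 5))
  expect_equal(px_dry / px_wet, 1.3, tolerance = 0.02)
})

test_that("closed pores open on drying according to p_open_on_drying", {
  m <- generate_cell_model(n_plates = 2, pores_per_plate = 25,
                           closed_fraction = 1, seed = 8)
  all_open <- apply_dehydration(m, dehydration_params(p_open_on_drying = 1,
                                                      seed = 1))
  expect_true(all(all_open$pores$open))
  none <- apply_dehydration(m, dehydration_params(p_open_on_drying = 0,
                                                  seed = 1))
  expect_true(all(!none$pores$open))
})

test_that("SEM render: constant field, disc area oracle, determinism", {
  m0 <- cell_model(field_size = c(1000, 1000))
  img0 <- render_sem(m0, pixel_size = 10, noise_sd = 0)
  expect_equal(max(img0$pixels) - min(img0$pixels), 0)
  expect_equal(img0$pixels[1, 1], 200)

  m1 <- one_pore_model(d = 200)
  img1 <- render_sem(m1, pixel_size = 10, noise_sd = 0)
  dark <- sum(img1$pixels < 110)
  r_px <- 10
  expect_lt(abs(dark - pi * r_px^2), 2 * pi * r_px)   # 1-px boundary band

  a <- render_sem(m1, pixel_size = 10, noise_sd = 4, seed = 42)
  b <- render_sem(m1, pixel_size = 10, noise_sd = 4, seed = 42)
  expect_identical(a$pixels, b$pixels)
  # closed pores are invisible in SEM
  mc <- one_pore_model(d = 200, open = FALSE)
  imgc <- render_sem(mc, pixel_size = 10, noise_sd = 0)
  expect_equal(max(imgc$pixels) - min(imgc$pixels), 0)
})

test_that("optical render: delta-PSF limit and photon conservation", {
  m <- one_pore_model(d = 300, field = 1500)
  p <- optical_params(psf_fwhm = 1e-3, pixel_size = 30, photon_budget = 100,
                      background = 0, noise = FALSE, oversample = 1)
  img <- render_optical(m, p)
  ind <- rasterize_indicator(m, 30)
  expect_equal(img$pixels, 100 * ind)

  p2 <- optical_params(psf_fwhm = 120, pixel_size = 30, photon_budget = 250,
                       background = 0, noise = FALSE, oversample = 2)
  img2 <- render_optical(m, p2)
  ind_fine <- rasterize_indicator(m, 15)
  expect_equal(sum(img2$pixels) / 250, sum(ind_fine) / 4,
               tolerance = 1e-6)   # normalized PSF conserves photons
  # a 100 nm pore under a 200 nm PSF keeps positive central intensity
  m2 <- one_pore_model(d = 100, field = 1500)
  img3 <- render_optical(m2, optical_params(psf_fwhm = 200, pixel_size = 30,
                                            photon_budget = 100, background = 0,
                                            noise = FALSE))
  expect_gt(min(img3$pixels), 0)
})

test_that("optical edge profile follows the Gaussian CDF", {
  m <- edge_model(field_w = 4000, field_h = 2000)
  sigma <- 100
  p <- optical_params(psf_fwhm = fencorr:::sigma_to_fwhm(sigma),
                      pixel_size = 20, photon_budget = 1000, background = 0,
                      noise = FALSE, oversample = 8)
  img <- render_optical(m, p)
  row <- nrow(img$pixels) %/% 2
  prof <- img$pixels[row, ]
  xs <- (seq_along(prof) - 0.5) * 20
  edge_x <- 2000   # gap occupies x > 2000 (circle curvature ~ 2 nm here)
  pred <- 1000 * pnorm((edge_x - xs) / sigma)
  interior <- xs > 500 & xs < 3500
  expect_lt(max(abs(prof - pred)[interior]), 0.01 * 1000)
})
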