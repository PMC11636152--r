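# Landmark registration and one-to-one pore matching

sim_matrix <- function(theta, s, dx, dy) {
  rbind(c(s * cos(theta), -s * sin(theta), dx),
        c(s * sin(theta), s * cos(theta), dy),
        c(0, 0, 1))
}

test_that("similarity fit recovers an exact transform", {
  M <- sim_matrix(30 * pi / 180, 2, 100, -50)
  a <- cbind(c(0, 500, 200, 800), c(0, 100, 700, 900))
  b <- t(M %*% rbind(t(a), 1))[, 1:2]
  tr <- fit_transform(data.frame(x_a = a[, 1], y_a = a[, 2],
                                 x_b = b[, 1], y_b = b[, 2]), "similarity")
  expect_equal(tr$matrix, M, tolerance = 1e-9)
  expect_lt(tr$rms_residual, 1e-6)
  # identity landmark set -> identity matrix
  id <- fit_transform(data.frame(x_a = a[, 1], y_a = a[, 2],
                                 x_b = a[, 1], y_b = a[, 2]), "similarity")
  expect_equal(id$matrix, diag(3), tolerance = 1e-12)
})

test_that("similarity fit agrees with the procrustes cross-check under noise", {
  skip_if_not_installed("vegan")
  set.seed(2)
  M <- sim_matrix(0.4, 1.7, 40, 80)
  a <- matrix(runif(20, 0, 2000), 10)
  b <- t(M %*% rbind(t(a), 1))[, 1:2] + matrix(rnorm(20, 0, 5), 10)
  tr <- fit_transform(data.frame(x_a = a[, 1], y_a = a[, 2],
                                 x_b = b[, 1], y_b = b[, 2]), "similarity")
  scale_est <- sqrt(det(tr$matrix[1:2, 1:2]))
  expect_lt(abs(scale_est - 1.7) / 1.7, 0.01)
  pr <- vegan::procrustes(b, a)   # fits b ~ scale * a R + t
  expect_equal(scale_est, pr$scale, tolerance = 1e-6)
  expect_equal(tr$rms_residual, sqrt(pr$ss / nrow(a)), tolerance = 1e-6)
})

test_that("affine and projective fits recover their generating transforms", {
  A <- rbind(c(1.2, 0.3, 50), c(-0.1, 0.9, -20), c(0, 0, 1))
  a <- matrix(runif(16, 0, 1000), 8)
  b <- t(A %*% rbind(t(a), 1))[, 1:2]
  tra <- fit_transform(cbind(a, b), "affine")
  expect_equal(tra$matrix, unname(A), tolerance = 1e-9)

  H <- rbind(c(1.1, 0.2, 30), c(0.05, 0.95, -10), c(1e-4, -5e-5, 1))
  bh <- t(H %*% rbind(t(a), 1))
  bh <- bh[, 1:2] / bh[, 3]
  trp <- fit_transform(cbind(a, bh), "projective")
  expect_equal(trp$matrix / trp$matrix[3, 3], H / H[3, 3], tolerance = 1e-6)

  coll <- cbind(1:5, 2 * (1:5), 1:5, 2 * (1:5))
  expect_error(fit_transform(coll, "affine"), "degenerate|collinear")
})

test_that("map_points: identity, translation, round trip, infinity flag", {
  pts <- matrix(runif(10, 0, 100), 5)
  expect_equal(map_points(identity_transform(), pts), pts)

  tr <- fit_transform(data.frame(x_a = c(0, 1, 2), y_a = c(0, 1, 0),
                                 x_b = c(7, 8, 9), y_b = c(-3, -2, -3)),
                      "similarity")
  expect_equal(map_points(tr, pts), pts + rep(c(7, -3), each = 5),
               tolerance = 1e-9)

  H <- rbind(c(1.05, 0.1, 20), c(-0.02, 0.98, 5), c(2e-4, 1e-4, 1))
  a <- matrix(runif(12, 0, 500), 6)
  bh <- t(H %*% rbind(t(a), 1)); bh <- bh[, 1:2] / bh[, 3]
  trp <- fit_transform(cbind(a, bh), "projective")
  round_trip <- map_points(invert_transform(trp), map_points(trp, pts))
  expect_equal(round_trip, pts, tolerance = 1e-9)

  sing <- structure(list(matrix = rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 1)),
                         kind = "projective", rms_residual = 0,
                         n_landmarks = 0L), class = "planar_transform")
  expect_warning(map_points(sing, matrix(c(1, 0), 1)), "infinity")
})

fake_table <- function(xy, ids = seq_len(nrow(xy))) {
  as_pt <- data.frame(pore_id = ids, modality = "X", x_nm = xy[, 1],
                      y_nm = xy[, 2], area_nm2 = 100, d_eq_nm = 100,
                      d_min_nm = 90, d_max_nm = 110, roundness = 0.8,
                      class = "fenestration", plate_id = NA_integer_,
                      border_flag = FALSE)
  fencorr:::as_pore_table(as_pt, cell_mask_area = 1e6, modality = "X")
}

test_that("identical tables match one-to-one at distance zero", {
  set.seed(3)
  xy <- matrix(runif(40, 0, 5000), 20)
  t1 <- fake_table(xy)
  mt <- match_pores(t1, t1, identity_transform(), gate = 150)
  expect_equal(nrow(mt$pairs), 20)
  expect_equal(mt$pairs$pore_id_a, mt$pairs$pore_id_b)
  expect_equal(max(mt$pairs$distance_nm), 0)
  expect_length(mt$unmatched_a, 0)
})

test_that("gated assignment equals the exhaustive-permutation optimum", {
  gate <- 150
  for (s in 1:20) {
    set.seed(s)
    n <- 6
    base <- matrix(runif(2 * n, 0, 2000), n)
    while (min(dist(base)) < gate) base <- matrix(runif(2 * n, 0, 2000), n)
    jit <- base + matrix(runif(2 * n, -gate / 4, gate / 4) / sqrt(2), n)
    mt <- match_pores(fake_table(base), fake_table(jit),
                      identity_transform(), gate)
    oracle <- brute_force_match(base, jit, gate)
    expect_equal(nrow(mt$pairs), oracle$cardinality)
    expect_equal(cbind(mt$pairs$pore_id_a, mt$pairs$pore_id_b),
                 unname(oracle$pairs))
  }
})

test_that("displaced pores beyond the gate stay unmatched on both sides", {
  xy <- rbind(c(100, 100), c(900, 900))
  xy2 <- rbind(c(100, 100), c(900 + 500, 900))
  mt <- match_pores(fake_table(xy), fake_table(xy2), gate = 150)
  expect_equal(nrow(mt$pairs), 1)
  expect_equal(mt$unmatched_a, 2)
  expect_equal(mt$unmatched_b, 2)
  # empty inputs yield empty matches
  e <- match_pores(fake_table(xy)[0, ], fake_table(xy2), gate = 150)
  expect_equal(nrow(e$pairs), 0)
})

test_that("matching is one-to-one, symmetric, and beats greedy", {
  set.seed(9)
  na <- 30; nb <- 25
  pa <- matrix(runif(2 * na, 0, 3000), na)
  pb <- pa[sample(na, nb), ] + matrix(rnorm(2 * nb, 0, 60), nb)
  ta <- fake_table(pa); tb <- fake_table(pb)
  mt <- match_pores(ta, tb, gate = 150)
  expect_lte(nrow(mt$pairs), min(na, nb))
  expect_equal(anyDuplicated(mt$pairs$pore_id_a), 0)
  expect_equal(anyDuplicated(mt$pairs$pore_id_b), 0)

  # symmetry under swapping A and B
  mt_rev <- match_pores(tb, ta, gate = 150)
  got <- mt_rev$pairs[, c("pore_id_b", "pore_id_a")]
  names(got) <- c("pore_id_a", "pore_id_b")
  expect_equal(mt$pairs[, 1:2], got[order(got$pore_id_a), ],
               ignore_attr = TRUE)

  # optimal total distance <= greedy nearest-neighbour on the same graph
  d <- as.matrix(dist(rbind(pa, pb)))[1:na, na + (1:nb)]
  d[d > 150] <- Inf
  greedy <- 0; used <- logical(nb)
  for (i in order(apply(d, 1, min))) {
    j <- which.min(replace(d[i, ], used, Inf))
    if (is.finite(d[i, j]) && !used[j]) { used[j] <- TRUE; greedy <- greedy + d[i, j] }
  }
  expect_lte(sum(mt$pairs$distance_nm), greedy + 1e-9)
})

test_that("merged components are matched to the nearest and flagged", {
  pa <- rbind(c(500, 500))
  pb <- rbind(c(450, 500), c(560, 500))
  mt <- match_pores(fake_table(pa), fake_table(pb), gate = 150)
  expect_equal(nrow(mt$pairs), 1)
  expect_equal(mt$pairs$pore_id_b, 1)   # nearest of the two candidates
  expect_true(mt$pairs$merged_candidate)
})
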