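# AFM Quantitative Imaging (QI) synthesis: per-pixel approach force-distance
# curves over a tip-convolved surface, with Hertz contact mechanics and a
# compliant rim band around open pores that makes reconstructed pore
# diameters grow with load force (tip-induced dilation).
#
# Units: nm, pN.  Moduli are stored in Pa (1 Pa = 1e-6 pN/nm^2); cantilever
# spring constants in N/m (1 N/m = 1000 pN/nm); rim compliance in nm/nN
# (1 nm/nN = 1e-3 nm/pN).

#' AFM QI acquisition/sample parameters
#'
#' @param pixel_size nm per pixel (15-30 nm for sieve-plate imaging).
#' @param tip_radius nm; sharp imaging tips are 2-25 nm.
#' @param spring_constant cantilever spring constant, N/m.
#' @param ramp_length force-distance ramp length, nm (300-800 nm).
#' @param samples_per_curve samples per approach curve (>= 64).
#' @param membrane_modulus apparent Young's modulus of the membrane, Pa.
#' @param substrate_modulus modulus of the substrate exposed in open pores,
#'   Pa (effectively rigid).
#' @param rim_compliance extra linear compliance at the pore rim, nm/nN;
#'   decays with distance to the rim over `rim_decay`.
#' @param rim_decay decay length of the rim compliance, nm.
#' @param max_force maximal load force reached in each pixel, pN.
#' @param closed_depth_fraction closed pores are rendered as depressions of
#'   this fraction of the membrane height.
#' @param clearance starting tip-sample clearance of the ramp, nm.
#' @param force_noise Gaussian force noise sd, pN (0 = noiseless).
#' @param poisson_ratio Poisson ratio of the sample (soft matter: 0.5).
#' @param seed noise seed.
#' @export
afm_params <- function(pixel_size = 30, tip_radius = 20,
                       spring_constant = 0.1, ramp_length = 600,
                       samples_per_curve = 128,
                       membrane_modulus = 2e5, substrate_modulus = 2e9,
                       rim_compliance = 150, rim_decay = 20,
                       max_force = 310, closed_depth_fraction = 0.4,
                       clearance = 30, force_noise = 0,
                       poisson_ratio = 0.5, seed = 1L) {
  stopifnot(pixel_size > 0, tip_radius > 0, spring_constant > 0,
            ramp_length >= 300, ramp_length <= 800,
            samples_per_curve >= 64, membrane_modulus > 0,
            substrate_modulus > 0, rim_compliance >= 0, rim_decay > 0,
            max_force > 0, closed_depth_fraction > 0,
            closed_depth_fraction < 1, clearance >= 0)
  structure(as.list(environment()), class = "afm_params")
}

#' Fixation presets for QI synthesis
#'
#' "GA" (glutaraldehyde-fixed): stiff membrane with a nearly rigid rim, so
#' reconstructed fenestration diameters barely depend on load force.  "FA"
#' (formaldehyde-fixed): softer membrane with a compliant rim, so the tip
#' dilates fenestrations noticeably as the load force grows.
#'
#' @param name "GA" or "FA".
#' @param ... overrides passed to [afm_params()].
#' @export
qi_preset <- function(name = c("GA", "FA"), ...) {
  name <- match.arg(name)
  base <- if (name == "GA") {
    list(membrane_modulus = 2e5, rim_compliance = 150)
  } else {
    list(membrane_modulus = 1e5, rim_compliance = 1100)
  }
  do.call(afm_params, modifyList(base, list(...)))
}

# Grey-scale morphological dilation of a height map with a spherical tip:
# the surface traced by the tip apex is max over the tip footprint of
# (height + sphere profile).
tip_convolve <- function(height, tip_radius, pixel_size) {
  rpx <- floor(tip_radius / pixel_size)
  if (rpx < 1) return(height)
  nr <- nrow(height); nc <- ncol(height)
  out <- height
  for (du in -rpx:rpx) {
    for (dv in -rpx:rpx) {
      if (du == 0 && dv == 0) next
      d2 <- (du^2 + dv^2) * pixel_size^2
      if (d2 > tip_radius^2) next
      drop <- tip_radius - sqrt(tip_radius^2 - d2)
      rs <- pmin(pmax(seq_len(nr) + du, 1), nr)
      cs <- pmin(pmax(seq_len(nc) + dv, 1), nc)
      out <- pmax(out, height[rs, cs, drop = FALSE] - drop)
    }
  }
  out
}

# Per-pixel ground-truth maps: surface height, Hertz prefactor, linear rim
# compliance (nm/pN)
qi_sample_maps <- function(model, p) {
  px <- p$pixel_size
  H <- model$membrane_height
  w <- model$field_size[["width"]]; h <- model$field_size[["height"]]
  nc <- round(w / px); nr <- round(h / px)

  height <- matrix(H, nr, nc)
  open_objs <- rbind(model$pores[model$pores$open, , drop = FALSE], model$gaps)
  closed <- model$pores[!model$pores$open, , drop = FALSE]
  height[object_idx(open_objs, nr, nc, px)] <- 0
  height[object_idx(closed, nr, nc, px)] <- (1 - p$closed_depth_fraction) * H

  substrate <- height == 0
  modulus <- matrix(p$membrane_modulus, nr, nc)
  modulus[substrate] <- p$substrate_modulus
  A <- matrix(hertz_prefactor(p$membrane_modulus, p$tip_radius,
                              p$poisson_ratio), nr, nc)
  A[substrate] <- hertz_prefactor(p$substrate_modulus, p$tip_radius,
                                  p$poisson_ratio)

  cmap <- matrix(0, nr, nc)
  if (p$rim_compliance > 0 && nrow(open_objs) > 0) {
    reach <- 5 * p$rim_decay
    for (i in seq_len(nrow(open_objs))) {
      o <- open_objs[i, ]
      a <- o$axis_major / 2; b <- o$axis_minor / 2
      r0 <- max(1L, floor((o$y - a - reach) / px) + 1L)
      r1 <- min(nr, ceiling((o$y + a + reach) / px))
      c0 <- max(1L, floor((o$x - a - reach) / px) + 1L)
      c1 <- min(nc, ceiling((o$x + a + reach) / px))
      if (r0 > r1 || c0 > c1) next
      xs <- ((c0:c1) - 0.5) * px - o$x
      ys <- ((r0:r1) - 0.5) * px - o$y
      ct <- cos(o$orientation); st <- sin(o$orientation)
      u <- outer(ys * st, xs, function(yy, xx) yy + xx * ct)
      v <- outer(ys * ct, -xs, function(yy, xx) yy + xx * st)
      rho <- sqrt((u / a)^2 + (v / b)^2)
      rad <- sqrt(u^2 + v^2)
      dist <- ifelse(rho > 1, rad * (1 - 1 / rho), 0)  # distance outside rim
      cc <- (p$rim_compliance / 1000) * exp(-dist / p$rim_decay)
      cc[rho <= 1] <- 0                                # inside pore: substrate
      sub <- cmap[r0:r1, c0:c1, drop = FALSE]
      cmap[r0:r1, c0:c1] <- pmax(sub, cc)
    }
    cmap[substrate] <- 0
  }
  list(height = height, A = A, modulus = modulus, compliance = cmap,
       substrate = substrate)
}

# Vectorized inversion of s = delta + b * A * delta^(3/2) by bisection
solve_indentation <- function(s, bA, iters = 50) {
  lo <- numeric(length(s)); hi <- s
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- mid + bA * mid * sqrt(mid) > s
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Render an AFM QI force-curve map
#'
#' For every pixel of the model field, synthesizes an approach
#' force-distance curve over a shared piezo ramp: zero force until contact
#' at the local tip-convolved surface height, then spherical Hertz contact
#' against the local effective modulus (substrate inside open pores,
#' membrane elsewhere) plus a linear rim compliance that decays with
#' distance to the nearest open-pore rim.  Cantilever deflection
#' (force / spring constant) is part of the piezo-height bookkeeping, so
#' topography reconstruction must add it back.  Closed pores appear as
#' shallow depressions (default 40% of the membrane height).
#'
#' @param model a `cell_model`.
#' @param p an [afm_params()] (or [qi_preset()]) object.
#' @return an object of class `qi_map`: shared descending `piezo_height`
#'   (nm), `force` array (rows x cols x samples, pN), acquisition metadata
#'   and the ground-truth maps used to generate it.
#' @export
render_qi <- function(model, p = afm_params()) {
  stopifnot(inherits(model, "cell_model"), inherits(p, "afm_params"))
  maps <- qi_sample_maps(model, p)
  surface <- tip_convolve(maps$height, p$tip_radius, p$pixel_size)
  nr <- nrow(surface); nc <- ncol(surface)
  ns <- p$samples_per_curve
  k_pn <- spring_pN_per_nm(p$spring_constant)

  z_top <- max(surface) + p$clearance
  z <- seq(z_top, z_top - p$ramp_length, length.out = ns)

  hvec <- as.vector(surface)
  cvec <- as.vector(maps$compliance)
  Avec <- as.vector(maps$A)
  # Moduli >= 100 MPa indent < 1 nm at these forces and are treated as a
  # hard wall (pure cantilever deflection, F = k * (h - z)), which keeps
  # rigid-sample reconstruction exact under linear interpolation.
  rigid <- as.vector(maps$modulus) >= 1e8

  # Pixels sharing (height, prefactor, compliance, rigidity) share a curve;
  # away from pore rims the map is piecewise constant, so this collapses
  # most of the grid.
  key <- paste(hvec, Avec, cvec, rigid)
  uniq <- which(!duplicated(key))
  map <- match(key, key[uniq])

  hu <- hvec[uniq]; Au <- Avec[uniq]
  bAu <- (cvec[uniq] + 1 / k_pn) * Au
  ru <- rigid[uniq]
  nu <- length(uniq)

  s_mat <- outer(hu, z, "-")                     # nu x ns separations
  fu <- matrix(0, nu, ns)
  if (any(ru)) {
    sm <- s_mat[ru, , drop = FALSE]
    fu[ru, ] <- k_pn * pmax(sm, 0)
  }
  soft <- which(!ru)
  if (length(soft) > 0) {
    sm <- s_mat[soft, , drop = FALSE]
    inc <- which(sm > 0)
    if (length(inc) > 0) {
      bA_full <- matrix(bAu[soft], length(soft), ns)[inc]
      delta <- solve_indentation(sm[inc], bA_full)
      fsub <- matrix(0, length(soft), ns)
      fsub[inc] <- matrix(Au[soft], length(soft), ns)[inc] * delta * sqrt(delta)
      fu[soft, ] <- fsub
    }
  }
  force <- fu[map, , drop = FALSE]

  fmax <- force[, ns]
  if (any(fmax < p$max_force)) {
    stop(sprintf(paste0(
      "max_force %g pN unreachable within the %g nm ramp for %d pixels ",
      "(deepest shortfall %.0f pN); lengthen ramp_length"),
      p$max_force, p$ramp_length, sum(fmax < p$max_force),
      p$max_force - min(fmax)))
  }

  if (p$force_noise > 0) {
    force <- force + with_seed(p$seed, matrix(
      rnorm(length(force), 0, p$force_noise), nrow(force), ncol(force)))
  }

  structure(list(piezo_height = z,
                 force = array(force, c(nr, nc, ns)),
                 pixel_size = p$pixel_size,
                 spring_constant = p$spring_constant,
                 max_force = p$max_force,
                 meta = list(params = unclass(p)),
                 truth = list(height = maps$height, surface = surface,
                              compliance = maps$compliance)),
            class = "qi_map")
}

#' @export
print.qi_map <- function(x, ...) {
  d <- dim(x$force)
  cat(sprintf("<qi_map> %d x %d px at %g nm/px, %d samples/curve, max force %g pN\n",
              d[1], d[2], x$pixel_size, d[3], x$max_force))
  invisible(x)
}

#' Extract one force curve from a QI map
#'
#' @param qimap a `qi_map`.
#' @param row,col pixel indices (1-based).
#' @return a `force_curve`: list with `piezo_height` (nm, descending),
#'   `force` (pN) and `spring_constant` (N/m).
#' @export
qi_curve <- function(qimap, row, col) {
  stopifnot(inherits(qimap, "qi_map"))
  force_curve(qimap$piezo_height, qimap$force[row, col, ],
              qimap$spring_constant)
}

#' Construct a force curve
#'
#' @param piezo_height descending piezo heights, nm.
#' @param force forces, pN.
#' @param spring_constant N/m.
#' @export
force_curve <- function(piezo_height, force, spring_constant) {
  stopifnot(length(piezo_height) == length(force),
            length(force) >= 64, spring_constant > 0)
  if (any(diff(piezo_height) >= 0)) {
    stop("piezo_height must be strictly descending (approach curve)")
  }
  structure(list(piezo_height = as.numeric(piezo_height),
                 force = as.numeric(force),
                 spring_constant = spring_constant),
            class = "force_curve")
}
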