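# Processing of per-pixel force-distance curves: contact-point detection,
# topography reconstruction at a chosen load force, Hertz elasticity
# fitting, and force tomography of pore diameters.

#' Detect the contact point of an approach curve
#'
#' The baseline (median of the first 25% of samples, i.e. far from the
#' surface) is subtracted; the contact point is the largest piezo height at
#' which the force exceeds `k_noise * force_noise` sustained for at least
#' `min_run` samples.
#'
#' @param curve a [force_curve()].
#' @param force_noise force noise floor, pN; if 0, the baseline standard
#'   deviation (or a tiny floor for noiseless curves) is used.
#' @param k_noise threshold multiple of the noise floor.
#' @param min_run required run of consecutive above-threshold samples.
#' @return contact piezo height, nm.
#' @export
find_contact_point <- function(curve, force_noise = 0, k_noise = 3,
                               min_run = 3) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$force)
  nb <- max(4L, floor(n * 0.25))
  baseline <- median(curve$force[seq_len(nb)])
  f <- curve$force - baseline
  if (force_noise <= 0) {
    force_noise <- max(sd(curve$force[seq_len(nb)]), 1e-6)
  }
  thr <- k_noise * force_noise
  above <- f > thr
  if (min_run > 1) {
    run <- above
    for (j in seq_len(min_run - 1)) {
      run <- run & c(above[-seq_len(j)], rep(FALSE, j))
    }
  } else run <- above
  i <- which(run)
  if (length(i) == 0) stop("no contact within ramp")
  curve$piezo_height[i[1]]
}

#' Reconstruct topography at a load force
#'
#' For every pixel, the surface height is the piezo height at which the
#' approach force first reaches `load_force` (linear interpolation between
#' ramp samples) plus the cantilever deflection `load_force / k`, which
#' converts piezo position to tip position.  Pixels that never reach the
#' load force are marked invalid (NA) rather than silently filled.
#'
#' @param qimap a `qi_map`.
#' @param load_force load force, pN, in (0, max_force].
#' @param fill_invalid replace invalid pixels by the image maximum so the
#'   map can be segmented; the invalid count is kept in `meta`.
#' @return a [raster_image()] of heights (nm), modality "AFM_TOPO", with
#'   `meta$load_force`.
#' @export
reconstruct_topography <- function(qimap, load_force, fill_invalid = TRUE) {
  stopifnot(inherits(qimap, "qi_map"), load_force > 0)
  if (load_force > qimap$max_force) {
    stop(sprintf("load_force %g pN exceeds max_force %g pN",
                 load_force, qimap$max_force))
  }
  d <- dim(qimap$force)
  npix <- d[1] * d[2]; ns <- d[3]
  fm <- matrix(qimap$force, npix, ns)
  z <- qimap$piezo_height
  ge <- fm >= load_force
  i2 <- max.col(ge, ties.method = "first")
  valid <- ge[cbind(seq_len(npix), i2)]

  zf <- rep(NA_real_, npix)
  first <- valid & i2 == 1
  zf[first] <- z[1]
  mid <- which(valid & i2 > 1)
  if (length(mid) > 0) {
    i2m <- i2[mid]; i1m <- i2m - 1
    f1 <- fm[cbind(mid, i1m)]; f2 <- fm[cbind(mid, i2m)]
    # If the lower bracket sample is still pre-contact (zero force) the
    # segment spans the contact kink; interpolate on the first fully
    # post-contact segment instead, which is exact for a hard wall.
    kink <- f1 <= 0 & i2m < ns
    pk <- mid[kink]
    if (length(pk) > 0) {
      ik <- i2m[kink]
      f2k <- fm[cbind(pk, ik)]
      f3k <- fm[cbind(pk, ik + 1)]
      zf[pk] <- z[ik] + (load_force - f2k) * (z[ik + 1] - z[ik]) /
        (f3k - f2k)
    }
    po <- mid[!kink]
    zf[po] <- z[i1m[!kink]] + (load_force - f1[!kink]) *
      (z[i2m[!kink]] - z[i1m[!kink]]) / (f2[!kink] - f1[!kink])
  }
  deflection <- load_force / spring_pN_per_nm(qimap$spring_constant)
  heights <- matrix(zf + deflection, d[1], d[2])

  n_invalid <- sum(!valid)
  if (n_invalid > 0 && fill_invalid) {
    heights[is.na(heights)] <- max(heights, na.rm = TRUE)
  }
  raster_image(if (fill_invalid) heights else {
    heights[is.na(heights)] <- NaN; heights
  }, qimap$pixel_size, "AFM_TOPO",
  meta = list(load_force = load_force, n_invalid = n_invalid))
}

#' Fit the Hertz contact model to a force curve
#'
#' Least-squares fit of `F = (4/3) (E / (1 - nu^2)) sqrt(r) delta^(3/2)`
#' over `0 < F <= fit_force_cap`, with indentation
#' `delta = contact_height - (z + F/k)` (piezo height corrected for
#' cantilever deflection).  The contact height starts at the detected
#' contact point and is refined by minimizing the residual sum of squares
#' over a window of a few sample spacings; for each candidate the
#' prefactor has the closed-form solution
#' `A = sum(F delta^1.5) / sum(delta^3)`.
#'
#' @param curve a [force_curve()].
#' @param probe_radius indenter radius, nm (colloidal probes: ~3950 nm).
#' @param poisson_ratio sample Poisson ratio (soft matter: 0.5).
#' @param fit_force_cap only samples with force at or below this cap are
#'   fitted, pN (low-force analysis probes the cortical layer only).
#' @param force_noise noise floor passed to [find_contact_point()].
#' @param refine refine the contact height by local RSS minimization.
#' @return an object of class `hertz_fit`: apparent_modulus (Pa),
#'   contact_height (nm), probe_radius, poisson_ratio, fit_rms (pN),
#'   indentation_range (nm), n_fit.
#' @export
fit_hertz <- function(curve, probe_radius, poisson_ratio = 0.5,
                      fit_force_cap = 200, force_noise = 0, refine = TRUE) {
  stopifnot(inherits(curve, "force_curve"), probe_radius > 0,
            fit_force_cap > 0)
  if (fit_force_cap > max(curve$force)) {
    stop("fit_force_cap exceeds the maximal force in the curve")
  }
  z <- curve$piezo_height
  k_pn <- spring_pN_per_nm(curve$spring_constant)
  nb <- max(4L, floor(length(z) * 0.25))
  baseline <- median(curve$force[seq_len(nb)])
  f <- curve$force - baseline

  zc0 <- find_contact_point(curve, force_noise)
  tip <- z + f / k_pn

  fit_at <- function(zc) {
    delta <- zc - tip
    sel <- f > 0 & f <= fit_force_cap & delta > 0
    if (sum(sel) < 8) return(list(rss = Inf, n = sum(sel)))
    d32 <- delta[sel]^1.5
    A <- sum(f[sel] * d32) / sum(d32^2)
    resid <- f[sel] - A * d32
    list(rss = sum(resid^2), A = A, n = sum(sel),
         rms = sqrt(mean(resid^2)), drange = range(delta[sel]))
  }

  # Threshold crossing always trails the true contact, so the refinement
  # window is asymmetric (wider above) and extends upward if the optimum
  # lands on its boundary.
  dz <- abs(median(diff(z)))
  zc <- zc0
  if (refine) {
    hi <- zc0 + 6 * dz
    obj <- function(v) {
      r <- fit_at(v)$rss
      if (is.finite(r)) r else 1e300
    }
    for (tries in 1:10) {
      opt <- optimize(obj, interval = c(zc0 - 2 * dz, hi), tol = 1e-8)
      if (opt$objective >= 1e299) break
      if (opt$minimum < hi - 0.05 * dz) { zc <- opt$minimum; break }
      hi <- hi + 6 * dz
      zc <- opt$minimum
    }
  }
  res <- fit_at(zc)
  if (!is.finite(res$rss)) {
    stop(sprintf("fewer than 8 post-contact samples under the %g pN cap",
                 fit_force_cap))
  }
  E <- res$A * 3 * (1 - poisson_ratio^2) / (4 * sqrt(probe_radius)) * 1e6
  structure(list(apparent_modulus = E, contact_height = zc,
                 probe_radius = probe_radius, poisson_ratio = poisson_ratio,
                 fit_rms = res$rms, indentation_range = res$drange,
                 n_fit = res$n),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g Pa, contact %.1f nm, rms %.2g pN (n = %d)\n",
              x$apparent_modulus, x$contact_height, x$fit_rms, x$n_fit))
  invisible(x)
}

#' Hertz elasticity map over a QI grid
#'
#' Runs [fit_hertz()] on an evenly spaced sub-grid of pixels (the classic
#' 8 x 8 force-map layout by default) and summarizes the apparent moduli.
#' Per-pixel failures are flagged, not fatal.
#'
#' @param qimap a `qi_map`.
#' @param grid `c(m, n)` sub-grid dimensions (must fit in the map).
#' @inheritParams fit_hertz
#' @return data frame (row, col, apparent_modulus_Pa, contact_height_nm,
#'   fit_rms_pN, ok, message) with attributes `mean_modulus` and
#'   `median_modulus`.
#' @export
elasticity_map <- function(qimap, grid = c(8, 8), probe_radius,
                           poisson_ratio = 0.5, fit_force_cap = 200,
                           force_noise = 0) {
  stopifnot(inherits(qimap, "qi_map"), length(grid) == 2)
  d <- dim(qimap$force)
  if (any(grid > d[1:2])) stop("grid larger than the QI map")
  if (any(grid < 1)) {
    out <- data.frame(row = integer(0), col = integer(0),
                      apparent_modulus_Pa = numeric(0),
                      contact_height_nm = numeric(0), fit_rms_pN = numeric(0),
                      ok = logical(0), message = character(0))
    attr(out, "mean_modulus") <- NaN
    attr(out, "median_modulus") <- NaN
    return(out)
  }
  rows <- round(seq(1, d[1], length.out = grid[1]))
  cols <- round(seq(1, d[2], length.out = grid[2]))
  sel <- expand.grid(row = rows, col = cols)
  res <- lapply(seq_len(nrow(sel)), function(i) {
    tryCatch({
      ft <- fit_hertz(qi_curve(qimap, sel$row[i], sel$col[i]),
                      probe_radius, poisson_ratio, fit_force_cap, force_noise)
      data.frame(row = sel$row[i], col = sel$col[i],
                 apparent_modulus_Pa = ft$apparent_modulus,
                 contact_height_nm = ft$contact_height,
                 fit_rms_pN = ft$fit_rms, ok = TRUE, message = "")
    }, error = function(e) {
      data.frame(row = sel$row[i], col = sel$col[i],
                 apparent_modulus_Pa = NA_real_, contact_height_nm = NA_real_,
                 fit_rms_pN = NA_real_, ok = FALSE,
                 message = conditionMessage(e))
    })
  })
  out <- do.call(rbind, res)
  attr(out, "mean_modulus") <- mean(out$apparent_modulus_Pa, na.rm = TRUE)
  attr(out, "median_modulus") <- median(out$apparent_modulus_Pa, na.rm = TRUE)
  out
}

#' Force tomography of fenestration diameters
#'
#' Reconstructs the topography at each load force, segments it in AFM
#' depth-threshold mode, and reports the mean fenestration equivalent
#' diameter per force together with the percent change relative to the
#' first (near-contact) force.  Rising diameters with force indicate
#' tip-induced pore dilation (compliant rims); a rigid sample gives zero
#' change.
#'
#' @param qimap a `qi_map`.
#' @param forces ascending load forces, pN (classically 70, 140, 280).
#' @param seg a [segmentation_params()] object.
#' @return data frame (force_pN, n_pores, mean_d_eq_nm, pct_change).
#' @export
force_tomography <- function(qimap, forces = c(70, 140, 280),
                             seg = segmentation_params()) {
  stopifnot(inherits(qimap, "qi_map"), length(forces) >= 1)
  if (any(diff(forces) <= 0)) stop("forces must be ascending")
  rows <- lapply(forces, function(f) {
    topo <- tryCatch(reconstruct_topography(qimap, f),
                     error = function(e) {
                       stop(sprintf("reconstruction failed at %g pN: %s",
                                    f, conditionMessage(e)), call. = FALSE)
                     })
    tab <- segment_image(topo, seg)
    keep <- tab$class == "fenestration" & !tab$border_flag
    data.frame(force_pN = f, n_pores = sum(keep),
               mean_d_eq_nm = if (any(keep)) mean(tab$d_eq_nm[keep]) else NaN)
  })
  out <- do.call(rbind, rows)
  out$pct_change <- 100 * (out$mean_d_eq_nm - out$mean_d_eq_nm[1]) /
    out$mean_d_eq_nm[1]
  out
}
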