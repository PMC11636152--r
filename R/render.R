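# Renderers: turn ground-truth geometry into SEM-like and optical
# (SIM/STED-like) raster images.  Pixel convention: pixels[row, col],
# 0-based physical coordinates with the origin at the top-left pixel
# centre, so column c (1-based) has x = (c - 0.5) * pixel_size.

#' Construct a raster image container
#'
#' @param pixels numeric matrix (rows = y, cols = x).
#' @param pixel_size physical pixel size, nm.
#' @param modality one of "SEM", "SIM", "STED", "AFM_TOPO".
#' @param meta free-form metadata list.
#' @export
raster_image <- function(pixels, pixel_size, modality = "SEM", meta = list()) {
  stopifnot(is.matrix(pixels), pixel_size > 0, all(is.finite(pixels)))
  modality <- match.arg(modality, c("SEM", "SIM", "STED", "AFM_TOPO"))
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 modality = modality, meta = meta),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %s, %d x %d px at %g nm/px, range [%.3g, %.3g]\n",
              x$modality, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.raster_image <- function(x, ...) {
  graphics::image(t(x$pixels)[, nrow(x$pixels):1], col = grDevices::gray.colors(256),
                  asp = nrow(x$pixels) / ncol(x$pixels), axes = FALSE, ...)
  invisible(x)
}

# Linear indices of the pixels whose centres fall inside an ellipse
ellipse_idx <- function(nr, nc, cx, cy, a, b, theta, pixel_size) {
  r0 <- max(1L, as.integer(floor((cy - a) / pixel_size)))
  r1 <- min(nr, as.integer(ceiling((cy + a) / pixel_size + 1)))
  c0 <- max(1L, as.integer(floor((cx - a) / pixel_size)))
  c1 <- min(nc, as.integer(ceiling((cx + a) / pixel_size + 1)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  xs <- ((c0:c1) - 0.5) * pixel_size - cx
  ys <- ((r0:r1) - 0.5) * pixel_size - cy
  ct <- cos(theta); st <- sin(theta)
  # rotate pixel offsets into the ellipse frame
  u <- outer(ys * st, xs, function(yy, xx) yy + xx * ct)   # rows x cols
  v <- outer(ys * ct, -xs, function(yy, xx) yy + xx * st)
  inside <- which((u / a)^2 + (v / b)^2 <= 1, arr.ind = TRUE)
  if (nrow(inside) == 0) return(integer(0))
  (inside[, 1] + r0 - 1L) + as.double(inside[, 2] + c0 - 2L) * nr
}

object_idx <- function(objs, nr, nc, pixel_size) {
  if (nrow(objs) == 0) return(numeric(0))
  unlist(lapply(seq_len(nrow(objs)), function(i) {
    o <- objs[i, ]
    ellipse_idx(nr, nc, o$x, o$y, o$axis_major / 2, o$axis_minor / 2,
                o$orientation, pixel_size)
  }), use.names = FALSE)
}

# Membrane indicator raster: 1 on membrane (and over closed pores, which are
# invisible holes), 0 inside open pores and gaps.
rasterize_indicator <- function(model, pixel_size) {
  w <- model$field_size[["width"]]; h <- model$field_size[["height"]]
  nc <- round(w / pixel_size); nr <- round(h / pixel_size)
  if (nr < 1 || nc < 1) stop("pixel_size larger than the field")
  if (as.double(nr) * nc > 5e8) stop("field/pixel_size overflow: image would exceed 5e8 pixels")
  ind <- matrix(1, nr, nc)
  objs <- rbind(model$pores[model$pores$open, , drop = FALSE], model$gaps)
  ind[object_idx(objs, nr, nc, pixel_size)] <- 0
  ind
}

# Gaussian blur with replicated (edge-extended) boundary: rendered fields
# are crops of a larger membrane, not periodic tiles.  Small kernels use a
# separable shifted-sum convolution (fast at any image size); large ones
# use EBImage's FFT path on a replicate-padded matrix.
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px < 0.05) return(mat)
  r <- ceiling(3.5 * sigma_px)
  if (r <= 10) {
    w <- dnorm(-r:r, sd = sigma_px)
    w <- w / sum(w)
    out <- matrix(0, nrow(mat), ncol(mat))
    nc <- ncol(mat)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(nc) + j, 1), nc)
      out <- out + w[j + r + 1] * mat[, idx, drop = FALSE]
    }
    out2 <- matrix(0, nrow(mat), ncol(mat))
    nr <- nrow(mat)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(nr) + j, 1), nr)
      out2 <- out2 + w[j + r + 1] * out[idx, , drop = FALSE]
    }
    out2
  } else {
    ri <- pmin(pmax(seq_len(nrow(mat) + 2 * r) - r, 1), nrow(mat))
    ci <- pmin(pmax(seq_len(ncol(mat) + 2 * r) - r, 1), ncol(mat))
    padded <- mat[ri, ci, drop = FALSE]
    blurred <- EBImage::gblur(padded, sigma = sigma_px)   # circular on pad
    blurred[r + seq_len(nrow(mat)), r + seq_len(ncol(mat)), drop = FALSE]
  }
}

#' Render an SEM-like image
#'
#' Fixed-dried SEM imaging resolves fenestrations crisply at 9-10 nm pixel
#' size: the membrane renders bright, open pores and gaps dark, with a 1-px
#' Gaussian antialias and additive Gaussian detector noise.  Closed
#' (invagination-only) pores render as membrane: they are indistinguishable
#' in SEM.
#'
#' @param model a `cell_model` (use the dehydrated model for a fixed-dried
#'   image).
#' @param pixel_size nm per pixel (<= 10 nm recommended).
#' @param noise_sd additive Gaussian noise, gray levels on the 0-255 scale.
#' @param seed noise seed (bit-reproducible for a fixed seed).
#' @param membrane_level,pore_level gray levels of membrane and pores.
#' @return a `raster_image` on the 0-255 scale, modality "SEM".
#' @export
render_sem <- function(model, pixel_size = 10, noise_sd = 0, seed = NULL,
                       membrane_level = 200, pore_level = 20) {
  stopifnot(inherits(model, "cell_model"))
  ind <- rasterize_indicator(model, pixel_size)
  img <- pore_level + (membrane_level - pore_level) * ind
  img <- gaussian_blur(img, 1)
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  }
  img <- pmin(pmax(img, 0), 255)
  raster_image(img, pixel_size, "SEM",
               meta = list(noise_sd = noise_sd, seed = seed,
                           membrane_level = membrane_level,
                           pore_level = pore_level))
}

#' Optical rendering parameters
#'
#' @param psf_fwhm full width at half maximum of the Gaussian point spread
#'   function, nm (e.g. ~110 nm for SIM, ~60 nm for STED).
#' @param pixel_size nm per pixel (30 nm AFM/STED-style, 39 nm STED/SEM-style).
#' @param photon_budget expected photons per pixel on uniform membrane.
#' @param background expected background photons per pixel.
#' @param noise apply Poisson photon noise (disable for expected images).
#' @param oversample sub-pixel rasterization factor for the indicator.
#' @param seed noise seed.
#' @export
optical_params <- function(psf_fwhm = 110, pixel_size = 30,
                           photon_budget = 500, background = 5,
                           noise = TRUE, oversample = 4, seed = 1L) {
  stopifnot(psf_fwhm > 0, pixel_size > 0, photon_budget > 0, background >= 0,
            oversample >= 1)
  structure(list(psf_fwhm = psf_fwhm, pixel_size = pixel_size,
                 photon_budget = photon_budget, background = background,
                 noise = noise, oversample = as.integer(oversample),
                 seed = seed),
            class = "optical_params")
}

#' Render an optical (SIM/STED-like) image
#'
#' The ideal membrane indicator (1 on membrane, 0 in open pores and gaps;
#' closed pores count as membrane) is scaled to the photon budget,
#' convolved with a normalized Gaussian PSF of the given FWHM, sampled at
#' the pixel size, and subjected to Poisson photon noise over a constant
#' background.  Expected photons are conserved by the normalized PSF.
#'
#' @param model a `cell_model`.
#' @param p an [optical_params()] object.
#' @return a `raster_image` in photon counts, modality "SIM" (relabel via
#'   `modality` if STED-like parameters are used).
#' @param modality stored modality label, "SIM" or "STED".
#' @export
render_optical <- function(model, p = optical_params(), modality = "SIM") {
  stopifnot(inherits(model, "cell_model"), inherits(p, "optical_params"))
  if (p$psf_fwhm / p$pixel_size < 1) {
    message("render_optical: psf_fwhm < pixel_size (undersampled PSF)")
  }
  os <- p$oversample
  fine <- p$pixel_size / os
  ind <- rasterize_indicator(model, fine)
  sigma_px <- fwhm_to_sigma(p$psf_fwhm) / fine
  blurred <- gaussian_blur(ind, sigma_px)
  # bin down to the acquisition grid (mean over os x os blocks)
  nrF <- nrow(blurred); ncF <- ncol(blurred)
  nr <- nrF %/% os; nc <- ncF %/% os
  blurred <- blurred[seq_len(nr * os), seq_len(nc * os), drop = FALSE]
  binned <- block_mean(blurred, os)
  expected <- p$photon_budget * binned + p$background
  img <- if (p$noise) {
    with_seed(p$seed, matrix(rpois(length(expected), lambda = pmax(expected, 0)),
                             nrow(expected), ncol(expected)))
  } else expected
  raster_image(img, p$pixel_size, modality,
               meta = list(params = unclass(p), expected_sum = sum(expected)))
}

block_mean <- function(mat, k) {
  if (k == 1) return(mat)
  nr <- nrow(mat) %/% k; nc <- ncol(mat) %/% k
  a <- array(mat, c(k, nr, k, nc))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}
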