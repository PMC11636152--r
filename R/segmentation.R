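# Threshold-based segmentation of fenestrations ("negative" structures: a
# dark pore in a bright membrane) and per-pore morphometrics.

#' Segmentation parameters
#'
#' @param clip_percentiles lower/upper percentiles used by
#'   [normalize_contrast()].
#' @param threshold_fraction for optical modalities: the cut level is
#'   placed this fraction of the membrane-to-background drop *below* the
#'   membrane level, i.e. `t = membrane - f * (membrane - background)`.
#'   The default 0.75 is the midpoint between the maximum-intensity level
#'   and the half-maximum level of a blurred edge and displaces the mask
#'   edge into the pore by 0.674 PSF-sigma per side; `f = 0.5` sits exactly
#'   at the half-maximum and is unbiased for straight edges.
#' @param fixed_threshold optional fixed gray-level threshold (normalized
#'   scale) used for SEM instead of the Otsu split.
#' @param min_diameter records with equivalent diameter below this are
#'   classed "subresolution" (nm).
#' @param gap_diameter records at or above this are classed "gap" (nm).
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param afm_depth_fraction for AFM topography: pore = normalized height
#'   below this fraction of the membrane-to-floor drop.
#' @export
segmentation_params <- function(clip_percentiles = c(0.5, 99.5),
                                threshold_fraction = 0.75,
                                fixed_threshold = NULL,
                                min_diameter = 50,
                                gap_diameter = 350,
                                connectivity = 8,
                                afm_depth_fraction = 0.5) {
  stopifnot(length(clip_percentiles) == 2,
            clip_percentiles[1] < clip_percentiles[2],
            threshold_fraction > 0, threshold_fraction < 1,
            min_diameter < gap_diameter,
            connectivity %in% c(4, 8),
            afm_depth_fraction > 0, afm_depth_fraction < 1)
  structure(list(clip_percentiles = clip_percentiles,
                 threshold_fraction = threshold_fraction,
                 fixed_threshold = fixed_threshold,
                 min_diameter = min_diameter, gap_diameter = gap_diameter,
                 connectivity = as.integer(connectivity),
                 afm_depth_fraction = afm_depth_fraction),
            class = "segmentation_params")
}

#' Normalize image contrast
#'
#' Clips intensities at the given percentiles and rescales linearly to
#' \[0, 1\] (the per-image "contrast adjustment" step that precedes
#' thresholding).
#'
#' @param img a [raster_image()].
#' @param clip_percentiles percentile pair, e.g. `c(0.5, 99.5)`.
#' @return the normalized `raster_image`.
#' @export
normalize_contrast <- function(img, clip_percentiles = c(0.5, 99.5)) {
  stopifnot(inherits(img, "raster_image"))
  q <- quantile(img$pixels, clip_percentiles / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("no contrast: image is constant within the clip percentiles")
  px <- (pmin(pmax(img$pixels, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  img$pixels <- px
  img$meta$normalized <- TRUE
  img$meta$clip_levels <- q
  img
}

# Mode of a numeric vector by kernel density; tie-break toward higher x.
density_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  d <- density(x, n = 512)
  peaks <- which(d$y == max(d$y))
  d$x[max(peaks)]
}

#' Binarize a normalized image into a pore mask
#'
#' For optical modalities (SIM/STED) the membrane level is estimated as the
#' mode of the upper intensity mode and the background as the mode of the
#' lower one; the cut level is `membrane - threshold_fraction * (membrane -
#' background)` and pixels below it are pore.  For SEM an Otsu split is
#' used unless `fixed_threshold` is given; a unimodal histogram raises an
#' error suggesting `fixed_threshold`.  For AFM topography, pore = height
#' below `afm_depth_fraction` of the normalized membrane-to-floor drop.
#'
#' @param img a normalized [raster_image()] (see [normalize_contrast()]).
#' @param p a [segmentation_params()] object.
#' @return logical matrix, `TRUE` = pore.
#' @export
binarize <- function(img, p = segmentation_params()) {
  stopifnot(inherits(img, "raster_image"))
  px <- img$pixels
  if (min(px) < -1e-9 || max(px) > 1 + 1e-9) {
    stop("binarize expects a normalized image; run normalize_contrast() first")
  }
  t <- if (img$modality %in% c("SIM", "STED")) {
    split <- as.numeric(EBImage::otsu(EBImage::Image(px), range = c(0, 1)))
    membrane <- density_mode(px[px >= split])
    # The sub-split class mixes true background with partially filled pore
    # dips; restrict the background estimate to the deep tail so the
    # threshold does not drift onto the dip plateau.
    bg_pool <- px[px <= split / 2]
    background <- if (length(bg_pool) >= 50) density_mode(bg_pool) else min(px)
    membrane - p$threshold_fraction * (membrane - background)
  } else if (img$modality == "SEM") {
    if (!is.null(p$fixed_threshold)) {
      p$fixed_threshold
    } else {
      split <- as.numeric(EBImage::otsu(EBImage::Image(px), range = c(0, 1)))
      lo <- px[px < split]; hi <- px[px >= split]
      if (length(lo) == 0 || length(hi) == 0) {
        stop("unimodal histogram: Otsu split failed; supply fixed_threshold")
      }
      d <- density(px, n = 512)
      valley <- d$y[which.min(abs(d$x - split))]
      pk_lo <- max(d$y[d$x < split]); pk_hi <- max(d$y[d$x >= split])
      if (valley > 0.8 * min(pk_lo, pk_hi)) {
        stop("unimodal histogram: no clear membrane/pore separation; supply fixed_threshold")
      }
      split
    }
  } else { # AFM_TOPO: pores are deep; threshold a fixed fraction of the drop
    p$afm_depth_fraction
  }
  px < t
}

# Label connected components; EBImage::bwlabel is 4-connectivity, so for
# connectivity = 8 diagonally adjacent labels are merged with a union-find
# pass.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1) {
    nr <- nrow(lab); nc <- ncol(lab)
    a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal
    c1 <- lab[-nr, -1]; d1 <- lab[-1, -nc]   # down-left diagonal
    pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                   cbind(c1[c1 > 0 & d1 > 0 & c1 != d1], d1[c1 > 0 & d1 > 0 & c1 != d1]))
    if (nrow(pairs) > 0) {
      root <- uf_union_pairs(nlab, pairs[, 1], pairs[, 2])
      relab <- match(root, sort(unique(root)))
      lab[lab > 0] <- relab[lab[lab > 0]]
    }
  }
  lab
}

#' Measure pores from a binary mask
#'
#' Labels connected components at the configured connectivity and measures
#' each: area (pixel count times pixel area), equivalent-area diameter
#' `d_eq = sqrt(4 area / pi)`, ellipse axes from second-order central
#' moments (with the 1/12-pixel variance correction), roundness
#' `d_min / d_max`, and class ("subresolution" below `min_diameter`, "gap"
#' at or above `gap_diameter`, otherwise "fenestration").  Components
#' touching the image border are flagged `border_flag = TRUE` so that
#' downstream statistics can exclude truncated pores.
#'
#' @param mask logical matrix (`TRUE` = pore), e.g. from [binarize()].
#' @param pixel_size nm per pixel.
#' @param p a [segmentation_params()] object.
#' @param cell_mask optional logical matrix of the cell footprint; its area
#'   becomes the table's `cell_mask_area`.
#' @param modality modality label stored per record.
#' @return a `pore_table` data frame with columns pore_id, modality, x_nm,
#'   y_nm, area_nm2, d_eq_nm, d_min_nm, d_max_nm, roundness, class,
#'   plate_id, border_flag.
#' @export
extract_pores <- function(mask, pixel_size, p = segmentation_params(),
                          cell_mask = NULL, modality = "SEM") {
  stopifnot(is.matrix(mask), pixel_size > 0)
  mode(mask) <- "logical"
  cell_area <- if (is.null(cell_mask)) {
    length(mask) * pixel_size^2
  } else sum(cell_mask) * pixel_size^2

  lab <- label_components(mask, p$connectivity)
  n <- max(lab)
  if (n == 0) {
    return(as_pore_table(empty_pore_table(modality),
                         cell_mask_area = cell_area, modality = modality))
  }

  idx <- which(lab > 0)
  lv <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  r <- as.double(rc[, 1]); c <- as.double(rc[, 2])

  npx <- tabulate(lv, n)
  sr <- rowsum(r, lv)[, 1];  sc <- rowsum(c, lv)[, 1]
  srr <- rowsum(r * r, lv)[, 1]; scc <- rowsum(c * c, lv)[, 1]
  src <- rowsum(r * c, lv)[, 1]
  mr <- sr / npx; mc <- sc / npx
  # central second moments of the pixel set, + 1/12 for the pixel footprint
  vrr <- srr / npx - mr^2 + 1 / 12
  vcc <- scc / npx - mc^2 + 1 / 12
  vrc <- src / npx - mr * mc
  tr2 <- (vrr + vcc) / 2
  det <- sqrt(pmax(((vcc - vrr) / 2)^2 + vrc^2, 0))
  l1 <- tr2 + det; l2 <- pmax(tr2 - det, 1e-12)
  # a solid ellipse with semi-axis a has variance a^2/4 along that axis
  d_max <- 4 * sqrt(l1) * pixel_size
  d_min <- 4 * sqrt(l2) * pixel_size

  area <- npx * pixel_size^2
  d_eq <- 2 * sqrt(area / pi)

  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_flag <- seq_len(n) %in% border_labels[border_labels > 0]

  cls <- ifelse(d_eq < p$min_diameter, "subresolution",
                ifelse(d_eq >= p$gap_diameter, "gap", "fenestration"))

  tab <- data.frame(pore_id = seq_len(n), modality = modality,
                    x_nm = (mc - 0.5) * pixel_size,
                    y_nm = (mr - 0.5) * pixel_size,
                    area_nm2 = area, d_eq_nm = d_eq,
                    d_min_nm = d_min, d_max_nm = d_max,
                    roundness = d_min / d_max,
                    class = cls, plate_id = NA_integer_,
                    border_flag = border_flag)
  as_pore_table(tab, cell_mask_area = cell_area, modality = modality)
}

#' One-call segmentation of a raster image
#'
#' Convenience wrapper: [normalize_contrast()], [binarize()] and
#' [extract_pores()] in sequence.
#'
#' @inheritParams extract_pores
#' @param img a [raster_image()].
#' @return a `pore_table`.
#' @export
segment_image <- function(img, p = segmentation_params(), cell_mask = NULL) {
  norm <- normalize_contrast(img, p$clip_percentiles)
  mask <- binarize(norm, p)
  extract_pores(mask, img$pixel_size, p, cell_mask, modality = img$modality)
}
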