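# Ground-truth geometry of a fenestrated cell: sieve plates of clustered
# elliptical pores, micron-scale gaps, and a membrane of fixed height.
# All coordinates are physical nanometres; x runs right, y runs down, with
# the origin at the centre of the top-left pixel of any raster derived from
# the model.

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Truncated-normal draws on (lower, Inf) by rejection
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

#' Generate a ground-truth fenestrated cell model
#'
#' Draws sieve plates of clustered elliptical pores whose equivalent-area
#' diameters follow a Gaussian truncated to positive values, places them by
#' rejection sampling with a guaranteed clearance between pore boundaries,
#' and optionally adds micron-scale membrane gaps and closed
#' (invagination-only) pores.  The model is the shared ground truth for the
#' SEM-like, optical and AFM QI renderers, so every downstream measurement
#' can be checked against known geometry.
#'
#' @param field_size width and height of the membrane field, nm.
#' @param n_plates number of sieve plates.
#' @param pores_per_plate pores drawn per plate.
#' @param diameter_mean,diameter_sd Gaussian parameters of the equivalent
#'   diameter, nm (defaults follow typical wet-fixed fenestration
#'   distributions, 158 +/- 40 nm).
#' @param roundness_mean,roundness_sd Gaussian parameters of pore roundness
#'   (minor/major axis ratio), truncated to (0.2, 1].
#' @param n_gaps number of micron-scale gaps (axis_major >= 1000 nm).
#' @param closed_fraction fraction of pores that are closed invaginations
#'   (not holes through the membrane).
#' @param membrane_height membrane thickness, nm.
#' @param min_separation minimum clearance between pore boundaries, nm.
#' @param seed integer seed; identical inputs give identical models.
#' @param max_attempts rejection-sampling attempts per object before the
#'   generator gives up with an error naming the density limit.
#' @return An object of class `cell_model`: a list with `pores` and `gaps`
#'   data frames (id, x, y, axis_major, axis_minor, orientation, open,
#'   plate_id), a `plates` data frame, `field_size`, `membrane_height` and
#'   `cell_mask_area` (nm^2).
#' @export
generate_cell_model <- function(field_size = c(10000, 10000),
                                n_plates = 6,
                                pores_per_plate = 40,
                                diameter_mean = 158,
                                diameter_sd = 40,
                                roundness_mean = 0.83,
                                roundness_sd = 0.09,
                                n_gaps = 0,
                                closed_fraction = 0,
                                membrane_height = 150,
                                min_separation = 30,
                                seed = NULL,
                                max_attempts = 500) {
  stopifnot(length(field_size) == 2, all(field_size > 0),
            diameter_mean > 0, diameter_sd >= 0,
            closed_fraction >= 0, closed_fraction <= 1,
            membrane_height > 0)
  if (is.null(seed)) stop("'seed' is required: the generator is a reproducibility contract")

  with_seed(seed, {
    w <- field_size[1]; h <- field_size[2]
    n_pores <- n_plates * pores_per_plate

    # Plate radius sized so the pore *exclusion* area (pore footprint plus
    # the separation band) fills ~15% of the plate; rejection sampling then
    # converges comfortably.
    excl <- diameter_mean^2 + diameter_sd^2 +
      2 * min_separation * diameter_mean + min_separation^2
    plate_radius <- if (n_plates > 0) sqrt(pores_per_plate * excl / (4 * 0.15)) else 0

    plates <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                         radius = numeric(0))
    if (n_plates > 0) {
      # jittered-grid placement: deterministic capacity check, seeded jitter
      gx <- ceiling(sqrt(n_plates * w / h))
      gy <- ceiling(n_plates / gx)
      cell_w <- w / gx; cell_h <- h / gy
      room <- min(cell_w, cell_h) / 2 - plate_radius - min_separation
      if (room < 0) {
        stop(sprintf(paste0(
          "field %g x %g nm cannot hold %d plates of radius %.0f nm; ",
          "reduce n_plates or pores_per_plate, or enlarge the field"),
          w, h, n_plates, plate_radius))
      }
      slots <- expand.grid(ix = seq_len(gx), iy = seq_len(gy))[seq_len(n_plates), ]
      plates <- data.frame(
        id = seq_len(n_plates),
        x = (slots$ix - 0.5) * cell_w + runif(n_plates, -room, room),
        y = (slots$iy - 0.5) * cell_h + runif(n_plates, -room, room),
        radius = plate_radius)
    }

    pores <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        axis_major = numeric(0), axis_minor = numeric(0),
                        orientation = numeric(0), open = logical(0),
                        plate_id = integer(0))
    if (n_pores > 0) {
      d_eq <- rnorm_trunc(n_pores, diameter_mean, diameter_sd, lower = 0)
      rnd <- pmin(pmax(rnorm(n_pores, roundness_mean, roundness_sd), 0.2), 1)
      a_mj <- d_eq / sqrt(rnd)
      a_mn <- d_eq * sqrt(rnd)
      theta <- runif(n_pores, 0, pi)
      k <- 0
      xs <- numeric(n_pores); ys <- numeric(n_pores); pid <- integer(n_pores)
      for (p in seq_len(n_plates)) {
        pl <- plates[p, ]
        for (j in seq_len(pores_per_plate)) {
          k <- k + 1
          rmax <- pl$radius - a_mj[k] / 2
          if (rmax <= 0) stop(sprintf(
            "pore %d (major axis %.0f nm) larger than its plate", k, a_mj[k]))
          placed <- FALSE
          for (a in seq_len(max_attempts)) {
            rr <- sqrt(runif(1)) * rmax
            phi <- runif(1, 0, 2 * pi)
            cx <- pl$x + rr * cos(phi); cy <- pl$y + rr * sin(phi)
            prev <- seq_len(k - 1)
            if (k == 1 ||
                all(sqrt((xs[prev] - cx)^2 + (ys[prev] - cy)^2) >
                    (a_mj[prev] + a_mj[k]) / 2 + min_separation)) {
              xs[k] <- cx; ys[k] <- cy; pid[k] <- pl$id
              placed <- TRUE
              break
            }
          }
          if (!placed) stop(sprintf(paste0(
            "could not place pore %d after %d attempts: pore density in ",
            "plate %d exceeds the packing limit (reduce pores_per_plate ",
            "or diameter_mean)"), k, max_attempts, pl$id))
        }
      }
      open <- rep(TRUE, n_pores)
      n_closed <- round(closed_fraction * n_pores)
      if (n_closed > 0) open[sample.int(n_pores, n_closed)] <- FALSE
      pores <- data.frame(id = seq_len(n_pores), x = xs, y = ys,
                          axis_major = a_mj, axis_minor = a_mn,
                          orientation = theta, open = open, plate_id = pid)
    }

    gaps <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       axis_major = numeric(0), axis_minor = numeric(0),
                       orientation = numeric(0), open = logical(0),
                       plate_id = integer(0))
    if (n_gaps > 0) {
      for (g in seq_len(n_gaps)) {
        a_mj <- runif(1, 1000, 2500)
        a_mn <- a_mj * runif(1, 0.6, 0.9)
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          cx <- runif(1, a_mj / 2, w - a_mj / 2)
          cy <- runif(1, a_mj / 2, h - a_mj / 2)
          clear_plates <- nrow(plates) == 0 ||
            all(sqrt((plates$x - cx)^2 + (plates$y - cy)^2) >
                plates$radius + a_mj / 2 + min_separation)
          clear_gaps <- nrow(gaps) == 0 ||
            all(sqrt((gaps$x - cx)^2 + (gaps$y - cy)^2) >
                (gaps$axis_major + a_mj) / 2 + min_separation)
          if (clear_plates && clear_gaps) {
            gaps <- rbind(gaps, data.frame(
              id = n_pores + g, x = cx, y = cy, axis_major = a_mj,
              axis_minor = a_mn, orientation = runif(1, 0, pi),
              open = TRUE, plate_id = NA_integer_))
            placed <- TRUE
            break
          }
        }
        if (!placed) stop(sprintf(
          "could not place gap %d after %d attempts: field too crowded",
          g, max_attempts))
      }
    }

    structure(list(field_size = c(width = w, height = h),
                   plates = plates, pores = pores, gaps = gaps,
                   membrane_height = membrane_height,
                   cell_mask_area = w * h,
                   params = list(diameter_mean = diameter_mean,
                                 diameter_sd = diameter_sd,
                                 roundness_mean = roundness_mean,
                                 roundness_sd = roundness_sd,
                                 closed_fraction = closed_fraction,
                                 min_separation = min_separation,
                                 seed = seed)),
              class = "cell_model")
  })
}

#' Construct a cell model from explicit geometry
#'
#' Programmatic constructor for hand-specified models (the generator is
#' usually preferable).  `pores` and `gaps` are data frames with columns
#' id, x, y, axis_major, axis_minor, orientation, open, plate_id.
#'
#' @param field_size width/height, nm.
#' @param pores,gaps,plates geometry data frames (may be empty/NULL).
#' @param membrane_height membrane thickness, nm.
#' @export
cell_model <- function(field_size = c(5000, 5000), pores = NULL, gaps = NULL,
                       plates = NULL, membrane_height = 150) {
  blank <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      axis_major = numeric(0), axis_minor = numeric(0),
                      orientation = numeric(0), open = logical(0),
                      plate_id = integer(0))
  pores <- if (is.null(pores)) blank else as.data.frame(pores)
  gaps <- if (is.null(gaps)) blank else as.data.frame(gaps)
  plates <- if (is.null(plates)) {
    data.frame(id = integer(0), x = numeric(0), y = numeric(0),
               radius = numeric(0))
  } else as.data.frame(plates)
  if (nrow(pores) > 0) {
    stopifnot(all(pores$axis_minor <= pores$axis_major),
              all(pores$axis_minor > 0))
  }
  structure(list(field_size = c(width = field_size[1], height = field_size[2]),
                 plates = plates, pores = pores, gaps = gaps,
                 membrane_height = membrane_height,
                 cell_mask_area = field_size[1] * field_size[2],
                 params = list()),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %g x %g nm field, %d plates, %d pores (%d open), %d gaps\n",
              x$field_size[1], x$field_size[2], nrow(x$plates),
              nrow(x$pores), sum(x$pores$open), nrow(x$gaps)))
  invisible(x)
}

#' Dehydration parameters
#'
#' Parameters of the fixed-dried transformation: a uniform dilation factor
#' applied to open pore axes (cells stay spread on the coverslip, so centres
#' and field size are fixed), extra radial elongation of pores in the outer
#' annulus of each sieve plate, and a probability that a closed pore opens
#' on drying.
#'
#' @param lambda_dilation uniform axis dilation factor (> 0); 1.34 matches a
#'   34% diameter increase from wet-fixed to fixed-dried; presets 1.33 and
#'   1.38 correspond to the STED- and AFM-referenced experiments.
#' @param edge_fraction fraction of the plate radius forming the outer
#'   "edge" annulus, in [0, 1).
#' @param edge_elongation extra major-axis stretch (>= 1), applied radially,
#'   for pores in the edge annulus.
#' @param p_open_on_drying probability a closed pore opens during drying.
#' @param seed seed for the stochastic opening draw.
#' @export
dehydration_params <- function(lambda_dilation = 1.34, edge_fraction = 0.2,
                               edge_elongation = 1.3, p_open_on_drying = 0.5,
                               seed = 1L) {
  stopifnot(lambda_dilation > 0, edge_fraction >= 0, edge_fraction < 1,
            edge_elongation >= 1, p_open_on_drying >= 0, p_open_on_drying <= 1)
  structure(list(lambda_dilation = lambda_dilation,
                 edge_fraction = edge_fraction,
                 edge_elongation = edge_elongation,
                 p_open_on_drying = p_open_on_drying,
                 seed = seed),
            class = "dehydration_params")
}

#' Apply dehydration to a cell model
#'
#' Transforms a wet-fixed ground-truth model into its fixed-dried
#' counterpart.  Pore centres and the field are unchanged; every open
#' pore's axes are multiplied by `lambda_dilation`; pores whose centre lies
#' in the outer `edge_fraction` annulus of their plate are additionally
#' stretched by `edge_elongation` along the radial direction (their
#' roundness drops by the same factor); closed pores open with probability
#' `p_open_on_drying` and otherwise stay closed.  Gaps are left unchanged.
#'
#' @param model a `cell_model`.
#' @param p a [dehydration_params()] object.
#' @return the dried `cell_model`.
#' @export
apply_dehydration <- function(model, p = dehydration_params()) {
  stopifnot(inherits(model, "cell_model"), inherits(p, "dehydration_params"))
  pores <- model$pores
  if (nrow(pores) == 0) return(model)

  newly_open <- with_seed(p$seed, {
    !pores$open & runif(nrow(pores)) < p$p_open_on_drying
  })
  open_out <- pores$open | newly_open
  dilate <- open_out   # anything open in the dried state dilates

  pores$axis_major[dilate] <- pores$axis_major[dilate] * p$lambda_dilation
  pores$axis_minor[dilate] <- pores$axis_minor[dilate] * p$lambda_dilation

  if (p$edge_elongation > 1 && p$edge_fraction > 0 && nrow(model$plates) > 0) {
    pl <- model$plates[match(pores$plate_id, model$plates$id), ]
    dx <- pores$x - pl$x; dy <- pores$y - pl$y
    radial <- sqrt(dx^2 + dy^2)
    edge <- !is.na(pl$radius) & radial > (1 - p$edge_fraction) * pl$radius
    sel <- edge & dilate
    # radial stretch: the major axis aligns with the plate-radial direction
    pores$orientation[sel] <- atan2(dy[sel], dx[sel])
    pores$axis_major[sel] <- pores$axis_major[sel] * p$edge_elongation
  }
  pores$open <- open_out

  model$pores <- pores
  model$dehydration <- p
  model
}

#' Ground-truth pore table from a cell model
#'
#' Converts model geometry to the same measurement table the segmentation
#' stage emits, using closed-form ellipse formulas (area = pi*a*b/4,
#' equivalent diameter sqrt(a*b), roundness b/a).  Only open pores are
#' tabulated by default since closed invaginations are invisible to SEM and
#' optical modalities.
#'
#' @param model a `cell_model`.
#' @param modality label stored in the table ("GT" = ground truth).
#' @param include_closed include closed pores as well.
#' @param min_diameter,gap_diameter class thresholds, nm: records below
#'   `min_diameter` are "subresolution", at or above `gap_diameter` "gap".
#' @return a `pore_table` data frame (see [extract_pores()] for columns).
#' @export
pore_table <- function(model, modality = "GT", include_closed = FALSE,
                       min_diameter = 50, gap_diameter = 350) {
  stopifnot(inherits(model, "cell_model"))
  po <- model$pores
  if (!include_closed && nrow(po) > 0) po <- po[po$open, , drop = FALSE]
  all <- rbind(po, model$gaps)
  if (nrow(all) == 0) {
    tab <- empty_pore_table(modality)
  } else {
    d_eq <- sqrt(all$axis_major * all$axis_minor)
    cls <- ifelse(d_eq < min_diameter, "subresolution",
                  ifelse(d_eq >= gap_diameter, "gap", "fenestration"))
    tab <- data.frame(pore_id = all$id, modality = modality,
                      x_nm = all$x, y_nm = all$y,
                      area_nm2 = pi * all$axis_major * all$axis_minor / 4,
                      d_eq_nm = d_eq,
                      d_min_nm = all$axis_minor, d_max_nm = all$axis_major,
                      roundness = all$axis_minor / all$axis_major,
                      class = cls,
                      plate_id = all$plate_id,
                      border_flag = FALSE)
  }
  as_pore_table(tab, cell_mask_area = model$cell_mask_area,
                modality = modality)
}

empty_pore_table <- function(modality = "GT") {
  data.frame(pore_id = integer(0), modality = character(0),
             x_nm = numeric(0), y_nm = numeric(0), area_nm2 = numeric(0),
             d_eq_nm = numeric(0), d_min_nm = numeric(0),
             d_max_nm = numeric(0), roundness = numeric(0),
             class = character(0), plate_id = integer(0),
             border_flag = logical(0))
}

as_pore_table <- function(df, cell_mask_area = NA_real_, modality = NA, meta = list()) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$pore_id)) stop("pore_ids must be unique")
  structure(df, class = c("pore_table", "data.frame"),
            cell_mask_area = cell_mask_area, modality = modality, meta = meta)
}

#' @export
print.pore_table <- function(x, ...) {
  cat(sprintf("<pore_table> %d records (%s), cell mask %.3g um^2\n",
              nrow(x), paste(unique(x$modality), collapse = "/"),
              attr(x, "cell_mask_area") / 1e6))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 6), digits = 4)
  invisible(x)
}
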