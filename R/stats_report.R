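# Distributional statistics of fenestration morphometry: Gaussian peak
# fits of diameter histograms, roundness summaries, paired wet/dry
# regressions, dehydration percent changes, the wet/dry correction
# coefficient, and porosity/frequency.  All statistics are computed on the
# fenestration class only (50-350 nm); gaps and subresolution components
# are excluded, and so are border-truncated components.

stat_records <- function(table) {
  stopifnot(is.data.frame(table))
  table[table$class == "fenestration" & !table$border_flag, , drop = FALSE]
}

#' Fit a Gaussian to a diameter distribution
#'
#' Histograms the fenestration equivalent diameters at `bin_width` and fits
#' `A exp(-(x - mu)^2 / (2 sigma^2))` to the bin counts by nonlinear least
#' squares (initialized at the mode bin, the sample sd and the max count).
#' The fitted `mu` is the "mean at the peak of the distribution".  If the
#' fit does not converge, or a single Gaussian explains less than 60% of
#' the count variance (e.g. a bimodal histogram), the sample mean/sd are
#' returned with `fallback = TRUE`.
#'
#' @param table a `pore_table`.
#' @param bin_width histogram bin width, nm.
#' @param values optional: fit these values instead of the table's
#'   `d_eq_nm` column.
#' @param min_records minimum number of fenestration records.
#' @return an object of class `gaussian_fit`: `mu`, `sigma`, `amplitude`,
#'   `n`, `bin_width`, `bin_centers`, `counts`, `fit_rms`, `fallback`,
#'   `sample_mean`, `sample_sd`.
#' @export
fit_diameter_distribution <- function(table, bin_width = 10, values = NULL,
                                      min_records = 30) {
  x <- if (is.null(values)) stat_records(table)$d_eq_nm else values
  if (length(x) < min_records) {
    stop(sprintf("need at least %d fenestration records, got %d",
                 min_records, length(x)))
  }
  b0 <- floor(min(x) / bin_width) * bin_width
  b1 <- ceiling(max(x) / bin_width) * bin_width
  if (b1 <= b0) b1 <- b0 + bin_width
  h <- hist(x, breaks = seq(b0, b1, by = bin_width), plot = FALSE,
            include.lowest = TRUE)
  ctr <- h$mids; cnt <- h$counts

  mu0 <- ctr[which.max(cnt)]
  sd0 <- max(sd(x), bin_width / 2)
  a0 <- max(cnt)
  fit <- tryCatch(
    minpack.lm::nlsLM(cnt ~ A * exp(-(ctr - mu)^2 / (2 * sigma^2)),
                      start = list(A = a0, mu = mu0, sigma = sd0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  fallback <- is.null(fit)
  if (!fallback) {
    cf <- coef(fit)
    resid <- cnt - predict(fit)
    r2 <- 1 - sum(resid^2) / sum((cnt - mean(cnt))^2)
    bad_peak <- !is.finite(cf[["mu"]]) || cf[["sigma"]] <= 0 ||
      cf[["mu"]] < min(x) || cf[["mu"]] > max(x) ||
      abs(cf[["mu"]] - mean(x)) > max(abs(cf[["sigma"]]), 2 * bin_width)
    # The explained-variance check flags bimodal/misfit histograms; it is
    # only meaningful when bins are well populated (Poisson bin noise
    # alone drags R^2 down on sparse histograms).
    bad_fit <- max(cnt) >= 30 && (!is.finite(r2) || r2 < 0.6)
    if (bad_peak || bad_fit) fallback <- TRUE
  }
  if (fallback) {
    mu <- mean(x); sigma <- sd(x); A <- max(cnt)
    rms <- NA_real_
  } else {
    mu <- cf[["mu"]]; sigma <- abs(cf[["sigma"]]); A <- cf[["A"]]
    rms <- sqrt(mean(resid^2))
  }
  structure(list(mu = mu, sigma = sigma, amplitude = A, n = length(x),
                 bin_width = bin_width, bin_centers = ctr, counts = cnt,
                 fit_rms = rms, fallback = fallback,
                 sample_mean = mean(x), sample_sd = sd(x)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> peak mu = %.4g +/- %.3g (n = %d%s)\n",
              x$mu, x$sigma, x$n,
              if (x$fallback) ", fallback: sample moments" else ""))
  invisible(x)
}

#' @export
plot.gaussian_fit <- function(x, main = "diameter distribution", ...) {
  graphics::barplot(x$counts, names.arg = round(x$bin_centers),
                    space = 0, main = main, ...)
  xs <- seq(0.5, length(x$bin_centers) - 0.5, length.out = 200)
  mu_i <- (x$mu - x$bin_centers[1]) / x$bin_width + 0.5
  sd_i <- x$sigma / x$bin_width
  graphics::lines(xs, x$amplitude * exp(-(xs - mu_i)^2 / (2 * sd_i^2)),
                  lwd = 2)
  invisible(x)
}

#' Roundness distribution summary
#'
#' Histogram of roundness (minor/major axis ratio, in (0, 1]) at bin width
#' 0.05, with the sample mean and sd.
#'
#' @param table a `pore_table`.
#' @param bin_width histogram bin width on the roundness axis.
#' @return list with `mean`, `sd`, `n`, `bin_centers`, `counts`.
#' @export
roundness_stats <- function(table, bin_width = 0.05) {
  r <- stat_records(table)$roundness
  if (length(r) == 0) {
    return(list(mean = NaN, sd = NaN, n = 0L,
                bin_centers = numeric(0), counts = integer(0)))
  }
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  h <- hist(pmin(r, 1), breaks = breaks, plot = FALSE)
  list(mean = mean(r), sd = sd(r), n = length(r),
       bin_centers = h$mids, counts = h$counts)
}

#' Paired regression between matched pores of two modalities
#'
#' Ordinary least squares of the B-side value on the A-side value (free
#' intercept) over one-to-one matched fenestration pairs, with Pearson's r.
#' A slope above 1 on the wet->dry diameter pairing quantifies dehydration
#' dilation; areas scale with the square of the dilation factor.
#'
#' @param matches a `match_table` from [match_pores()].
#' @param table_a,table_b the matched `pore_table`s.
#' @param variable "d_eq" (diameter) or "area".
#' @param min_pairs minimum pair count.
#' @return list (`n_pairs`, `slope`, `intercept`, `pearson_r`, `variable`).
#' @export
paired_regression <- function(matches, table_a, table_b,
                              variable = c("d_eq", "area"), min_pairs = 10) {
  variable <- match.arg(variable)
  col <- if (variable == "d_eq") "d_eq_nm" else "area_nm2"
  prs <- matches$pairs
  ia <- match(prs$pore_id_a, table_a$pore_id)
  ib <- match(prs$pore_id_b, table_b$pore_id)
  keep <- table_a$class[ia] == "fenestration" &
    table_b$class[ib] == "fenestration" &
    !table_a$border_flag[ia] & !table_b$border_flag[ib]
  xa <- table_a[[col]][ia[keep]]
  xb <- table_b[[col]][ib[keep]]
  if (length(xa) < min_pairs) {
    stop(sprintf("need at least %d matched fenestration pairs, got %d",
                 min_pairs, length(xa)))
  }
  if (var(xa) == 0 || var(xb) == 0) stop("zero variance in paired values")
  ft <- lm.fit(cbind(1, xa), xb)
  list(n_pairs = length(xa),
       slope = unname(ft$coefficients[2]),
       intercept = unname(ft$coefficients[1]),
       pearson_r = cor(xa, xb),
       variable = variable)
}

#' Percent change between wet and dry peak diameters
#'
#' `100 (mu_dry - mu_wet) / mu_wet`, rounded half-up to the nearest integer
#' for reporting (e.g. 158 -> 212 nm is a 34% increase).
#'
#' @param mu_wet,mu_dry fitted peak means, nm (wet-fixed and fixed-dried).
#' @param rounded return the integer-rounded value.
#' @export
percent_change <- function(mu_wet, mu_dry, rounded = TRUE) {
  if (any(mu_wet <= 0)) stop("mu_wet must be positive")
  pct <- 100 * (mu_dry - mu_wet) / mu_wet
  if (rounded) round_half_up(pct) else pct
}

#' Wet/dry correction coefficient
#'
#' Per experiment pair, the ratio of the wet-technique peak mean to the
#' SEM (fixed-dried) peak mean, and the mean ratio over pairs; multiplying
#' a dried-sample SEM mean by this coefficient predicts the expected
#' wet-technique mean.  Ratios are reported both at full precision and
#' rounded half-up to 2 decimals (158/212 gives 0.7453, reported as 0.75).
#'
#' @param fits list of `c(wet, dry)` peak-mean pairs (numeric length-2
#'   vectors, or lists of two `gaussian_fit` objects).
#' @return list with `ratios`, `ratios_2dp`, `mean_ratio`, `mean_ratio_2dp`.
#' @export
correction_coefficient <- function(fits) {
  if (length(fits) == 0) stop("need at least one wet/dry pair")
  get_mu <- function(f) if (inherits(f, "gaussian_fit")) f$mu else as.numeric(f)
  ratios <- vapply(fits, function(pair) {
    mus <- vapply(pair, get_mu, numeric(1))
    mus[1] / mus[2]
  }, numeric(1))
  list(ratios = ratios,
       ratios_2dp = round_half_up(ratios, 2),
       mean_ratio = mean(ratios),
       mean_ratio_2dp = round_half_up(mean(ratios), 2))
}

#' Porosity and fenestration frequency
#'
#' Porosity = total fenestration area / cell mask area (unitless);
#' frequency = fenestration count per square micron.  Gaps and
#' subresolution components are excluded by the class filter.
#'
#' @param table a `pore_table`.
#' @param cell_mask_area cell (or image) area in nm^2; defaults to the
#'   table's own attribute.
#' @return list (`porosity`, `frequency_per_um2`, `n`).
#' @export
porosity_frequency <- function(table, cell_mask_area = NULL) {
  area <- cell_mask_area %||% attr(table, "cell_mask_area")
  if (is.null(area) || !is.finite(area) || area <= 0) {
    stop("cell_mask_area must be positive")
  }
  rec <- stat_records(table)
  list(porosity = sum(rec$area_nm2) / area,
       frequency_per_um2 = nrow(rec) / (area / 1e6),
       n = nrow(rec))
}

#' Assemble the summary report
#'
#' Collects per-modality Gaussian fits, roundness summaries, paired
#' statistics, percent changes, correction coefficients and
#' porosity/frequency into a single deterministic JSON-ready list.
#' Missing components are listed under `missing` and the report is still
#' emitted.
#'
#' @param tables named list of `pore_table`s (per modality).
#' @param matches optional `match_table`.
#' @param diameter_fits named list of `gaussian_fit`s.
#' @param roundness named list of [roundness_stats()] results.
#' @param paired named list of [paired_regression()] results.
#' @param percent_changes,correction named entries as computed.
#' @param params free-form parameter/seed record for provenance.
#' @param path optional path; if given, the report is written as JSON.
#' @return the report list, invisibly if written.
#' @export
build_report <- function(tables = list(), matches = NULL,
                         diameter_fits = list(), roundness = list(),
                         paired = list(), percent_changes = list(),
                         correction = NULL, params = list(), path = NULL) {
  empty <- length(tables) == 0
  counts <- lapply(tables, function(t) {
    as.list(table(factor(t$class,
                         levels = c("fenestration", "gap", "subresolution"))))
  })
  porosity <- lapply(tables, function(t) {
    if (nrow(stat_records(t)) == 0) list(porosity = 0, frequency_per_um2 = 0, n = 0)
    else porosity_frequency(t)
  })
  gf <- lapply(diameter_fits, function(f) {
    f[c("mu", "sigma", "amplitude", "n", "bin_width", "fallback")]
  })
  missing <- c(
    if (length(tables) == 0) "tables",
    if (is.null(matches)) "matches",
    if (length(diameter_fits) == 0) "diameter_fits")
  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("fencorr")),
    empty = empty,
    params = params,
    counts = counts,
    porosity = porosity,
    diameter_fits = gf,
    roundness = lapply(roundness, function(r) r[c("mean", "sd", "n")]),
    paired = paired,
    percent_changes = percent_changes,
    correction = correction,
    n_matched = if (!is.null(matches)) nrow(matches$pairs) else 0L,
    missing = as.list(missing))
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}
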