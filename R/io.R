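# File formats: 16-bit grayscale TIFF + JSON sidecar for rasters, CSV for
# pore/match/landmark tables, JSON for transforms and reports, HDF5 for QI
# force-curve stacks.  Physical units are spelled out in column names
# (nm, nm2, pN) to prevent unit drift; the pixel size lives in the JSON
# sidecar because TIFF resolution-tag conventions differ between
# microscope exporters.

SCHEMA_VERSION <- "1.0"

sidecar_path <- function(path) paste0(path, ".json")

#' Write a raster image as 16-bit TIFF plus JSON sidecar
#'
#' Intensities are affinely mapped to the 16-bit range; the offset and
#' scale are recorded in the sidecar so [read_raster()] restores physical
#' values (exactly for data with up to 65536 evenly spaced levels, to
#' 1/65535 of the range otherwise).
#'
#' @param img a [raster_image()].
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param extra extra fields merged into the sidecar (e.g. seed, params).
#' @export
write_raster <- function(img, path, extra = list()) {
  stopifnot(inherits(img, "raster_image"))
  lo <- min(img$pixels); hi <- max(img$pixels)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img$pixels - lo) / scale, path, bits.per.sample = 16L)
  meta <- c(list(schema_version = SCHEMA_VERSION,
                 pixel_size_nm = img$pixel_size,
                 modality = img$modality,
                 offset = lo, scale = scale),
            extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster image written by [write_raster()]
#'
#' @param path TIFF path (grayscale, 8- or 16-bit, single page); the JSON
#'   sidecar `<path>.json` must provide `pixel_size_nm` and `modality`.
#' @export
read_raster <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf(paste0("missing sidecar %s: required keys pixel_size_nm, ",
                        "modality"), sc))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("pixel_size_nm", "modality")) {
    if (is.null(meta[[key]])) stop(sprintf("sidecar missing required key %s", key))
  }
  check_schema(meta$schema_version)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 1) stop("multi-page TIFF unsupported")
  px <- pages[[1]]
  if (length(dim(px)) == 3) stop("RGB TIFF unsupported: expected grayscale")
  offset <- meta$offset %||% 0
  scale <- meta$scale %||% 1
  raster_image(px * scale + offset, meta$pixel_size_nm, meta$modality,
               meta = meta)
}

check_schema <- function(v) {
  if (is.null(v)) stop("schema_version missing")
  major <- as.integer(strsplit(as.character(v), ".", fixed = TRUE)[[1]][1])
  if (major > 1L) stop(sprintf("unknown schema major version %s", v))
  invisible(TRUE)
}

PORE_TABLE_COLS <- c("pore_id", "modality", "x_nm", "y_nm", "area_nm2",
                     "d_eq_nm", "d_min_nm", "d_max_nm", "roundness",
                     "class", "plate_id", "border_flag")

#' Write a pore table as CSV
#'
#' Columns, exactly: pore_id, modality, x_nm, y_nm, area_nm2, d_eq_nm,
#' d_min_nm, d_max_nm, roundness, class, plate_id, border_flag.  A JSON
#' sidecar carries cell_mask_area and schema version.
#'
#' @param table a `pore_table`.
#' @param path CSV path.
#' @export
write_pore_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  df <- as.data.frame(table)[, PORE_TABLE_COLS]
  stopifnot(all(df$class %in% c("fenestration", "gap", "subresolution")))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                            cell_mask_area_nm2 = attr(table, "cell_mask_area"),
                            modality = attr(table, "modality")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pore table written by [write_pore_table()]
#' @param path CSV path.
#' @export
read_pore_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), PORE_TABLE_COLS)) {
    stop("unexpected pore-table columns: ", paste(names(df), collapse = ", "))
  }
  area <- NA_real_; modality <- NA
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    check_schema(meta$schema_version)
    area <- meta$cell_mask_area_nm2 %||% NA_real_
    modality <- meta$modality %||% NA
  }
  as_pore_table(df, cell_mask_area = area, modality = modality)
}

#' Write/read landmark pairs (x_a, y_a, x_b, y_b in nm)
#' @param landmarks data frame with columns x_a, y_a, x_b, y_b.
#' @param path CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- as.data.frame(landmarks)[, c("x_a", "y_a", "x_b", "y_b")]
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write/read a planar transform as JSON
#' @param t a `planar_transform`.
#' @param path JSON path.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "planar_transform"))
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION, kind = t$kind,
                            matrix = t$matrix, rms_residual = t$rms_residual,
                            n_landmarks = t$n_landmarks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(j$schema_version)
  structure(list(matrix = matrix(unlist(j$matrix), 3, 3), kind = j$kind,
                 rms_residual = j$rms_residual,
                 n_landmarks = j$n_landmarks %||% 0L),
            class = "planar_transform")
}

#' Write a match table (pairs CSV + transform JSON sidecar)
#' @param matches a `match_table`.
#' @param path CSV path for the pairs.
#' @export
write_match_table <- function(matches, path) {
  stopifnot(inherits(matches, "match_table"))
  write.csv(matches$pairs, path, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                            gate_nm = matches$gate,
                            unmatched_a = matches$unmatched_a,
                            unmatched_b = matches$unmatched_b,
                            transform = list(kind = matches$transform$kind,
                                             matrix = matches$transform$matrix,
                                             rms_residual = matches$transform$rms_residual)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_match_table
#' @export
read_match_table <- function(path) {
  pairs <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  check_schema(meta$schema_version)
  tr <- structure(list(matrix = matrix(unlist(meta$transform$matrix), 3, 3),
                       kind = meta$transform$kind,
                       rms_residual = meta$transform$rms_residual,
                       n_landmarks = 0L),
                  class = "planar_transform")
  structure(list(pairs = pairs,
                 unmatched_a = unlist(meta$unmatched_a) %||% integer(0),
                 unmatched_b = unlist(meta$unmatched_b) %||% integer(0),
                 transform = tr, gate = meta$gate_nm),
            class = "match_table")
}

#' Write a QI force-curve map to its HDF5 container
#'
#' Layout: group `/meta` with attributes spring_constant_N_per_m,
#' pixel_size_nm, rows, cols, samples_per_curve, max_force_pN and
#' schema_version; dataset `/piezo_height_nm` (shared descending ramp);
#' dataset `/force_pN` with dimensions (rows, cols, samples).
#'
#' @param qimap a `qi_map`.
#' @param path HDF5 path (overwritten if present).
#' @export
write_qi <- function(qimap, path) {
  stopifnot(inherits(qimap, "qi_map"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "meta")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "meta")
  d <- dim(qimap$force)
  rhdf5::h5writeAttribute(qimap$spring_constant, gid, "spring_constant_N_per_m")
  rhdf5::h5writeAttribute(qimap$pixel_size, gid, "pixel_size_nm")
  rhdf5::h5writeAttribute(d[1], gid, "rows")
  rhdf5::h5writeAttribute(d[2], gid, "cols")
  rhdf5::h5writeAttribute(d[3], gid, "samples_per_curve")
  rhdf5::h5writeAttribute(qimap$max_force, gid, "max_force_pN")
  rhdf5::h5writeAttribute(SCHEMA_VERSION, gid, "schema_version")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  rhdf5::h5write(qimap$piezo_height, path, "piezo_height_nm")
  rhdf5::h5write(qimap$force, path, "force_pN")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a QI force-curve map from its HDF5 container
#' @param path HDF5 path written by [write_qi()].
#' @export
read_qi <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  meta <- rhdf5::h5readAttributes(path, "meta")
  if (is.null(meta$schema_version)) stop("schema_version missing from /meta")
  check_schema(meta$schema_version)
  z <- as.numeric(rhdf5::h5read(path, "piezo_height_nm"))
  force <- rhdf5::h5read(path, "force_pN")
  d <- dim(force)
  expect <- c(meta$rows, meta$cols, meta$samples_per_curve)
  if (!all(d == expect)) {
    stop(sprintf("force_pN dims (%s) inconsistent with /meta (%s)",
                 paste(d, collapse = "x"), paste(expect, collapse = "x")))
  }
  if (length(z) != d[3]) stop("piezo_height_nm length inconsistent with /meta")
  structure(list(piezo_height = z, force = force,
                 pixel_size = as.numeric(meta$pixel_size_nm),
                 spring_constant = as.numeric(meta$spring_constant_N_per_m),
                 max_force = as.numeric(meta$max_force_pN),
                 meta = meta, truth = NULL),
            class = "qi_map")
}
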