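#' Georeferenced climate grid
#'
#' A minimal in-memory raster: a numeric matrix whose rows run north to
#' south (row 1 is the northernmost) and columns west to east, on a square
#' cell of `cellsize` degrees anchored at the lower-left corner
#' (`xllcorner`, `yllcorner`). Cells equal to the `nodata` sentinel are
#' held as `NA` internally and propagate through all arithmetic.
#'
#' @param values Numeric matrix (NA marks nodata).
#' @param cellsize Cell size, degrees.
#' @param xllcorner,yllcorner Lower-left corner, degrees.
#' @param nodata Sentinel written on output (default -9999).
#' @return Object of class `climate_grid`.
#' @export
climate_grid <- function(values, cellsize, xllcorner = 0, yllcorner = 0,
                         nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(values), cellsize > 0)
  structure(list(values = values, cellsize = as.numeric(cellsize),
                 xllcorner = as.numeric(xllcorner),
                 yllcorner = as.numeric(yllcorner),
                 nodata = as.numeric(nodata)),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid: %d rows x %d cols, cellsize %g deg, ll corner (%g, %g), %d nodata cells\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xllcorner,
              x$yllcorner, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$xllcorner - b$xllcorner) < tol &&
    abs(a$yllcorner - b$yllcorner) < tol
}

#' Read a climate raster
#'
#' Supports the two flat text/binary dialects common for gridded monthly
#' climate layers:
#'
#' * `ascii_grid` (.asc): a header of `ncols, nrows, xllcorner, yllcorner,
#'   cellsize, NODATA_value` followed by `nrows` rows of `ncols`
#'   whitespace-separated values, northernmost row first.
#' * `flat_binary` (.flt): 4-byte little-endian IEEE floats in the same
#'   row-major order, with a sidecar `.hdr` carrying the same header keys
#'   plus `byteorder`. Only `LSBFIRST` (little-endian) is supported;
#'   `MSBFIRST` files are rejected explicitly rather than silently
#'   misread.
#'
#' @param path Path to the `.asc` or `.flt` file (for `flat_binary`, the
#'   `.hdr` sidecar is found by swapping the extension).
#' @param format `"ascii_grid"` or `"flat_binary"`; by default inferred
#'   from the file extension.
#' @return A [climate_grid()].
#' @export
read_grid <- function(path, format = c("auto", "ascii_grid", "flat_binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.flt$", path, ignore.case = TRUE))
      "flat_binary" else "ascii_grid"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "ascii_grid") read_ascii_grid(path) else read_flt_grid(path)
}

parse_grid_header <- function(lines, path) {
  hdr <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 2L)
      stop("malformed header line in ", path, ": '", ln, "'", call. = FALSE)
    key <- tolower(parts[1])
    hdr[[key]] <- parts[2]
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[req]]))
      stop("missing header key '", req, "' in ", path, call. = FALSE)
    val <- suppressWarnings(as.numeric(hdr[[req]]))
    if (is.na(val))
      stop("non-numeric header value for '", req, "' in ", path,
           call. = FALSE)
    hdr[[req]] <- val
  }
  hdr$nodata_value <- if (!is.null(hdr$nodata_value))
    as.numeric(hdr$nodata_value) else -9999
  hdr
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*[A-Za-z]", lines)
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  hdr <- parse_grid_header(lines[seq_len(n_hdr)], path)
  body <- lines[-seq_len(n_hdr)]
  body <- body[trimws(body) != ""]
  if (length(body) != hdr$nrows)
    stop("dimension error in ", path, ": expected ", hdr$nrows,
         " data rows, found ", length(body), call. = FALSE)
  rows <- lapply(body, function(ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  nc <- lengths(rows)
  if (any(nc != hdr$ncols))
    stop("dimension error in ", path, ": row with ", nc[nc != hdr$ncols][1],
         " values, expected ", hdr$ncols, call. = FALSE)
  m <- do.call(rbind, rows)
  m[m == hdr$nodata_value] <- NA_real_
  climate_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
               hdr$nodata_value)
}

read_flt_grid <- function(path) {
  hdr_path <- sub("\\.flt$", ".hdr", path, ignore.case = TRUE)
  if (!file.exists(hdr_path))
    stop("missing .hdr sidecar for ", path, call. = FALSE)
  hdr_lines <- readLines(hdr_path)
  hdr <- parse_grid_header(
    hdr_lines[!grepl("^\\s*byteorder", hdr_lines, ignore.case = TRUE)],
    hdr_path)
  bo <- grep("^\\s*byteorder", hdr_lines, ignore.case = TRUE, value = TRUE)
  if (length(bo) > 0L) {
    order <- toupper(trimws(strsplit(trimws(bo[1]), "\\s+")[[1]][2]))
    if (order != "LSBFIRST")
      stop("unsupported flat-binary byte order '", order,
           "' (only LSBFIRST little-endian is supported)", call. = FALSE)
  }
  n <- hdr$nrows * hdr$ncols
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(vals) != n)
    stop("dimension error in ", path, ": expected ", n, " floats, read ",
         length(vals), call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  # sentinel comparison after 4-byte round-trip loses double precision
  m[abs(m - hdr$nodata_value) < 1e-4 * max(1, abs(hdr$nodata_value))] <- NA_real_
  climate_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
               hdr$nodata_value)
}

#' Write a climate grid as an ESRI ASCII raster
#'
#' Emits the header keys in the canonical order (`ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value`) followed by the value rows,
#' northernmost first, with 6 significant digits and a locale-independent
#' `.` decimal mark. NA cells are written as the nodata sentinel.
#'
#' @param grid A [climate_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  m <- grid$values
  fmt <- function(x) formatC(x, format = "g", digits = 6, decimal.mark = ".")
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", fmt(grid$xllcorner)),
    paste("yllcorner", fmt(grid$yllcorner)),
    paste("cellsize", fmt(grid$cellsize)),
    paste("NODATA_value", fmt(grid$nodata)))
  body <- apply(m, 1L, function(row) {
    row[is.na(row)] <- grid$nodata
    paste(fmt(row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a climate grid as flat binary (.flt + .hdr)
#'
#' 4-byte little-endian floats in row-major (north-first) order with a
#' sidecar header declaring `byteorder LSBFIRST`.
#'
#' @inheritParams write_ascii_grid
#' @param path Output `.flt` path; the `.hdr` is written alongside.
#' @export
write_flt_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr_path <- sub("\\.flt$", ".hdr", path, ignore.case = TRUE)
  if (identical(hdr_path, path)) hdr_path <- paste0(path, ".hdr")
  fmt <- function(x) formatC(x, format = "g", digits = 6, decimal.mark = ".")
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", fmt(grid$xllcorner)),
    paste("yllcorner", fmt(grid$yllcorner)),
    paste("cellsize", fmt(grid$cellsize)),
    paste("NODATA_value", fmt(grid$nodata)),
    "byteorder LSBFIRST"), hdr_path)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Bundle monthly min/max temperature grids into a stack
#'
#' @param tmin,tmax Lists of 12 [climate_grid()] layers (January-December)
#'   of monthly minimum and maximum temperature (deg C). All 24 layers
#'   must share geometry, and `tmin <= tmax` cell-wise wherever both are
#'   valid.
#' @return Object of class `monthly_stack`.
#' @export
monthly_stack <- function(tmin, tmax) {
  stopifnot(is.list(tmin), is.list(tmax),
            length(tmin) == 12L, length(tmax) == 12L)
  ref <- tmin[[1]]
  for (g in c(tmin, tmax)) {
    if (!inherits(g, "climate_grid"))
      stop("all layers must be climate_grid objects", call. = FALSE)
    if (!same_geometry(ref, g))
      stop("dimension error: monthly layers do not share geometry",
           call. = FALSE)
  }
  for (mo in 1:12) {
    bad <- tmin[[mo]]$values > tmax[[mo]]$values
    if (any(bad, na.rm = TRUE))
      stop("tmin exceeds tmax in month ", mo, call. = FALSE)
  }
  structure(list(tmin = tmin, tmax = tmax), class = "monthly_stack")
}

#' @export
print.monthly_stack <- function(x, ...) {
  cat("monthly_stack: 12 tmin + 12 tmax layers of",
      nrow(x$tmin[[1]]$values), "x", ncol(x$tmin[[1]]$values), "cells\n")
  invisible(x)
}

#' Read a monthly stack from per-month raster files
#'
#' Expects 12 files per directory named so that lexicographic order after
#' zero-padding is month order (e.g. `tmin_01.asc` ... `tmin_12.asc`).
#'
#' @param tmin_dir,tmax_dir Directories holding the 12 monthly layers each.
#' @param format Passed to [read_grid()].
#' @return A [monthly_stack()].
#' @export
read_monthly_stack <- function(tmin_dir, tmax_dir, format = "auto") {
  load_dir <- function(d) {
    files <- sort(list.files(d, pattern = "\\.(asc|flt)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) != 12L)
      stop("expected 12 raster files in ", d, ", found ", length(files),
           call. = FALSE)
    lapply(files, read_grid, format = format)
  }
  monthly_stack(load_dir(tmin_dir), load_dir(tmax_dir))
}
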