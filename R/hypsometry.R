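#' Bathymetry grid
#'
#' Container for a gridded lake-bed elevation model. Bed elevations are metres
#' above a common vertical datum; `NA` cells are land (no data). Depth of a
#' cell is `surface_elevation - bed_elevation`; cells whose bed sits exactly
#' at (or above) the surface are treated as land. An optional logical
#' `exclusion_mask` (`TRUE` = excluded) removes areas that are physically wet
#' but outside the study basin, e.g. a connected marsh the study species does
#' not enter.
#'
#' @param bed_elevation numeric matrix of bed elevations (m above datum);
#'   `NA` = land/no-data.
#' @param cell_size grid resolution in metres (square cells).
#' @param surface_elevation water-surface elevation above the same datum
#'   (m); default 75.
#' @param exclusion_mask optional logical matrix, `TRUE` for cells excluded
#'   from the lake.
#' @return An object of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(bed_elevation, cell_size, surface_elevation = 75,
                            exclusion_mask = NULL) {
  if (!is.matrix(bed_elevation) || !is.numeric(bed_elevation))
    stopf("bed_elevation must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stopf("cell_size must be a single positive number")
  if (!is.numeric(surface_elevation) || length(surface_elevation) != 1L)
    stopf("surface_elevation must be a single number")
  wet <- is.finite(bed_elevation)
  if (any(bed_elevation[wet] > surface_elevation))
    stopf("bed elevations above the water surface: lower surface_elevation or mask those cells")
  if (!is.null(exclusion_mask)) {
    if (!is.logical(exclusion_mask) || !identical(dim(exclusion_mask), dim(bed_elevation)))
      stopf("exclusion_mask must be a logical matrix with the same dimensions as bed_elevation")
  }
  structure(list(bed_elevation = bed_elevation, cell_size = cell_size,
                 surface_elevation = surface_elevation,
                 exclusion_mask = exclusion_mask),
            class = "bathymetry_grid")
}

# depth-below-surface matrix; land/excluded cells are NA
grid_depth <- function(grid) {
  d <- grid$surface_elevation - grid$bed_elevation
  d[!is.finite(d) | d <= 0] <- NA_real_
  if (!is.null(grid$exclusion_mask)) d[grid$exclusion_mask] <- NA_real_
  d
}

#' Hypsographic curve from a bathymetry grid
#'
#' Computes lake area as a function of depth and integrates it to per-stratum
#' volumes on 1-m strata. Stratum `i` spans depths `(i-1, i]` m below the
#' surface; its volume is the trapezoid `(area(i-1) + area(i)) / 2 * 1 m`,
#' where `area(d)` is the planar area of all non-excluded cells at least `d`
#' metres deep. The curve extends to the deepest wet cell.
#'
#' @param grid a [bathymetry_grid()].
#' @return A data frame of class `hypsographic_curve` with columns `stratum`,
#'   `depth_top_m`, `area_top_m2`, `area_bottom_m2`, `volume_m3`, and
#'   attributes `total_volume` (m^3, the exact sum of stratum volumes),
#'   `surface_area` (m^2) and `cell_size`.
#' @examples
#' bed <- matrix(72, 10, 10)          # flat bottom, 3 m deep at 75 m surface
#' g <- bathymetry_grid(bed, cell_size = 100)
#' compute_hypsographic_curve(g)
#' @export
compute_hypsographic_curve <- function(grid) {
  if (!inherits(grid, "bathymetry_grid")) stopf("grid must be a bathymetry_grid")
  depth <- grid_depth(grid)
  d <- depth[is.finite(depth)]
  if (length(d) == 0L) stopf("no wet cells: the grid contains no lake")
  cs2 <- grid$cell_size^2
  n <- as.integer(ceiling(max(d)))
  # area(k) for k = 0..n: cells at least k m deep
  area <- vapply(0:n, function(k) sum(d >= k) * cs2, numeric(1))
  vol <- (area[-(n + 1L)] + area[-1L]) / 2  # 1-m strata
  out <- data.frame(stratum = seq_len(n),
                    depth_top_m = 0:(n - 1L),
                    area_top_m2 = area[-(n + 1L)],
                    area_bottom_m2 = area[-1L],
                    volume_m3 = vol)
  structure(out,
            class = c("hypsographic_curve", "data.frame"),
            total_volume = sum(vol),
            surface_area = area[1L],
            cell_size = grid$cell_size)
}

#' Total lake volume of a hypsographic curve
#' @param curve a `hypsographic_curve`.
#' @return Total volume in m^3.
#' @export
total_volume <- function(curve) {
  if (!inherits(curve, "hypsographic_curve")) stopf("not a hypsographic_curve")
  attr(curve, "total_volume")
}

#' Read an ESRI ASCII grid
#'
#' Minimal reader for the `.asc` interchange format (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header followed by row-major values,
#' first row = northernmost).
#'
#' @param path path to the `.asc` file.
#' @return A list with `data` (numeric matrix, row 1 = north), `cell_size`,
#'   `xll`, `yll`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stopf("ASCII grid header missing '%s'", key)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stopf("ASCII grid: expected %d values, found %d",
          hdr$ncols * hdr$nrows, length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(data = m, cell_size = hdr$cellsize,
       xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

#' Write an ESRI ASCII grid
#'
#' @param data numeric matrix (row 1 = north).
#' @param path output path.
#' @param cell_size cell size in metres.
#' @param xll,yll lower-left corner coordinates.
#' @param nodata value used to encode `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(data, path, cell_size, xll = 0, yll = 0,
                             nodata = -9999) {
  m <- data
  m[!is.finite(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %g", xll), sprintf("yllcorner %g", yll),
           sprintf("cellsize %g", cell_size), sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a bathymetry grid from an ESRI ASCII file
#'
#' @inheritParams read_ascii_grid
#' @param surface_elevation water-surface elevation (m above the grid datum).
#' @param exclusion_path optional path to a second ASCII grid of the same
#'   shape; cells with value > 0 are excluded from the lake.
#' @return A [bathymetry_grid()] with coordinate attributes `xll`, `yll`.
#' @export
read_bathymetry <- function(path, surface_elevation = 75, exclusion_path = NULL) {
  g <- read_ascii_grid(path)
  excl <- NULL
  if (!is.null(exclusion_path)) {
    e <- read_ascii_grid(exclusion_path)
    if (!identical(dim(e$data), dim(g$data)))
      stopf("exclusion grid dimensions differ from the bathymetry grid")
    excl <- !is.na(e$data) & e$data > 0
  }
  out <- bathymetry_grid(g$data, cell_size = g$cell_size,
                         surface_elevation = surface_elevation,
                         exclusion_mask = excl)
  attr(out, "xll") <- g$xll
  attr(out, "yll") <- g$yll
  out
}

#' Write a hypsographic curve to CSV
#' @param curve a `hypsographic_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypsographic_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
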