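#' Bivariate normal reference bandwidth
#'
#' The ad hoc plug-in bandwidth for an isotropic bivariate normal kernel:
#' `h = sigma * n^(-1/6)` with `sigma = sqrt((var(x) + var(y)) / 2)`. Scale
#' equivariant and invariant to point order.
#'
#' @param points matrix or data.frame with columns `x`, `y` (m); at least 5
#'   points.
#' @return bandwidth in meters.
#' @export
reference_bandwidth <- function(points) {
  x <- points[, "x"]; y <- points[, "y"]
  n <- length(x)
  if (n < 5) stop("need at least 5 points for the reference bandwidth")
  s2 <- (stats::var(x) + stats::var(y)) / 2
  if (s2 <= 0) stop("all points identical: bandwidth undefined")
  sqrt(s2) * n^(-1 / 6)
}

#' Kernel utilization density on a grid
#'
#' Evaluates the bivariate normal kernel density estimate at cell centers
#' of a regular grid and renormalizes so the cell masses sum to one. The
#' grid defaults to the point extent plus a `3.5 h` margin at resolution
#' `h / 3` (coarsened if that would exceed `max_cells`). Evaluation uses
#' the separability of the isotropic Gaussian kernel, so cost is
#' `O(n * (rows + cols))`.
#'
#' @param points matrix/data.frame with `x`, `y` (m).
#' @param h bandwidth (m); default [reference_bandwidth()].
#' @param grid optional list `(origin, cell_size, n_rows, n_cols)`;
#'   built automatically when `NULL`.
#' @param margin_h margin around the point extent, in bandwidths; must be
#'   at least 3 or boundary clipping is rejected.
#' @param max_cells cap on grid size.
#' @return object of class `ud_grid`: geometry fields plus `density`
#'   (matrix, cell probability mass / cell area) and `h`.
#' @export
kde_density <- function(points, h = NULL, grid = NULL, margin_h = 3.5,
                        max_cells = 250000) {
  x <- points[, "x"]; y <- points[, "y"]
  if (is.null(h)) h <- reference_bandwidth(points)
  if (is.null(grid)) {
    m <- margin_h * h
    cell <- h / 3
    ext_x <- diff(range(x)) + 2 * m
    ext_y <- diff(range(y)) + 2 * m
    if (ext_x * ext_y / cell^2 > max_cells) {
      cell <- sqrt(ext_x * ext_y / max_cells)
    }
    grid <- list(origin = c(min(x) - m, min(y) - m), cell_size = cell,
                 n_rows = ceiling(ext_y / cell),
                 n_cols = ceiling(ext_x / cell))
  }
  xc <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  yc <- grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  n <- length(x)
  Wx <- stats::dnorm(outer(xc, x, "-") / h)  # n_cols x n
  Wy <- stats::dnorm(outer(yc, y, "-") / h)  # n_rows x n
  dens <- (Wy %*% t(Wx)) / (n * h^2)
  mass <- sum(dens) * grid$cell_size^2
  if (1 - mass > 1e-3) {
    stop(sprintf(
      "grid margin too small: %.2f%% of kernel mass clipped (need < 0.1%%)",
      100 * (1 - mass)))
  }
  dens <- dens / mass
  structure(list(origin = grid$origin, cell_size = grid$cell_size,
                 n_rows = grid$n_rows, n_cols = grid$n_cols,
                 density = dens, h = h, n = n),
            class = "ud_grid")
}

#' Isopleth mask of a utilization distribution
#'
#' Sorts cells by density (descending, ties broken deterministically in cell
#' order) and keeps the minimal prefix whose cumulative probability mass
#' reaches `level` — the smallest cell set containing that fraction of the
#' utilization distribution.
#'
#' @param ud a `ud_grid` from [kde_density()].
#' @param level isopleth level in (0, 1); 0.95 delineates the standard
#'   seasonal range.
#' @return list with `mask` (logical matrix), `area_km2`, `level`.
#' @export
isopleth <- function(ud, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("isopleth level must lie strictly between 0 and 1")
  }
  v <- as.vector(ud$density)
  ord <- order(-v, seq_along(v))  # ties: cell storage order
  mass <- cumsum(v[ord]) * ud$cell_size^2
  k <- which(mass >= level)[1]
  if (is.na(k)) k <- length(v)
  mask <- matrix(FALSE, ud$n_rows, ud$n_cols)
  mask[ord[seq_len(k)]] <- TRUE
  list(mask = mask, area_km2 = k * ud$cell_size^2 / 1e6, level = level)
}

#' Delineate a seasonal range
#'
#' Convenience wrapper: reference bandwidth, kernel density, and the 95%
#' isopleth for one animal-season-year's fixes.
#'
#' @param points fixes of one seasonal range (`x`, `y` in m).
#' @param id,season,year identifiers carried through to the result.
#' @param level isopleth level.
#' @param ... passed to [kde_density()].
#' @return object of class `seasonal_range`: `ud`, `mask`, `area_km2`,
#'   `h`, `n`, identifiers.
#' @export
delineate_range <- function(points, id = NA, season = NA, year = NA,
                            level = 0.95, ...) {
  h <- reference_bandwidth(points)
  ud <- kde_density(points, h = h, ...)
  iso <- isopleth(ud, level = level)
  structure(list(animal_id = id, season = season, year = year,
                 ud = ud, mask = iso$mask, area_km2 = iso$area_km2,
                 level = level, h = h, n = nrow(points)),
            class = "seasonal_range")
}

#' @export
print.seasonal_range <- function(x, ...) {
  cat("<seasonal_range> ", x$animal_id, " ", x$season, " yr", x$year,
      ": ", x$n, " fixes, h = ", round(x$h), " m, ",
      sprintf("%.1f km2 at %.0f%% isopleth\n", x$area_km2, 100 * x$level),
      sep = "")
  invisible(x)
}

#' Export a utilization density as a plain-text raster
#'
#' Writes the density grid of a `ud_grid` or `seasonal_range` as an ESRI
#' ASCII grid (`.asc`), the package's text raster format.
#'
#' @param ud a `ud_grid` or `seasonal_range`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ud_asc <- function(ud, path) {
  if (inherits(ud, "seasonal_range")) ud <- ud$ud
  hdr <- c(
    paste("ncols", ud$n_cols), paste("nrows", ud$n_rows),
    paste("xllcorner", ud$origin[1]), paste("yllcorner", ud$origin[2]),
    paste("cellsize", ud$cell_size), "NODATA_value -9999"
  )
  body <- apply(signif(ud$density[rev(seq_len(ud$n_rows)), , drop = FALSE],
                       7), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export an isopleth as GeoJSON
#'
#' Writes the isopleth cell set as a GeoJSON MultiPolygon of cell squares
#' (raster representation, not a traced contour), in the projected
#' coordinate system of the grid.
#'
#' @param range a `seasonal_range`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_isopleth_geojson <- function(range, path) {
  ud <- range$ud
  idx <- which(range$mask)
  r <- ((idx - 1) %% ud$n_rows) + 1
  cl <- ((idx - 1) %/% ud$n_rows) + 1
  cs <- ud$cell_size
  polys <- lapply(seq_along(idx), function(i) {
    x0 <- ud$origin[1] + (cl[i] - 1) * cs
    y0 <- ud$origin[2] + (r[i] - 1) * cs
    list(list(
      c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs), c(x0, y0 + cs),
      c(x0, y0)
    ))
  })
  gj <- list(
    type = "Feature",
    properties = list(animal_id = range$animal_id, season = range$season,
                      year = range$year, level = range$level,
                      area_km2 = range$area_km2),
    geometry = list(type = "MultiPolygon", coordinates = polys)
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
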