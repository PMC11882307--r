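#' Generate a synthetic covariate landscape
#'
#' Builds a flat projected grid (meters) carrying the covariate layers used by
#' the resource-selection pipeline: a five-class categorical landcover
#' (forest, herbaceous, crops, residential, other), Euclidean
#' distance-to-residential-development and distance-to-road surfaces, and a
#' seasonal NDVI stack at an 8-day compositing resolution. Landcover classes
#' are quantile bands of a smooth random field (a terrain-position proxy), so
#' development and crops sit in connected valley-like patches, class
#' proportions are met exactly, and patch size is controlled by the field's
#' wavelength; roads are straight transects rasterized onto the grid. All
#' layers share the grid geometry, so the object doubles as the extraction
#' source for both simulation and model fitting.
#'
#' @param n_rows,n_cols grid dimensions (cells); must be positive.
#' @param cell_size cell edge length in meters.
#' @param origin numeric length-2, x/y of the grid's lower-left corner (m).
#' @param prop named numeric of landcover class proportions; names must be
#'   exactly `forest, herbaceous, crops, residential, other`. Need not sum to
#'   one (normalized internally); realized cell proportions match exactly.
#' @param patch_km characteristic landcover patch diameter (km).
#' @param n_roads number of straight road transects.
#' @param n_ndvi_periods number of 8-day NDVI periods (46 covers a year).
#' @param ndvi_seasonal_amplitude mean amplitude of the within-year NDVI
#'   cycle (peak around midsummer).
#' @param seed integer seed; identical `(arguments, seed)` give bit-identical
#'   stacks.
#' @return an object of class `covariate_stack`: grid geometry, `landcover`
#'   (integer matrix with `levels` attribute), `dist_development` and
#'   `dist_roads` matrices (m), `ndvi` array (`n_rows x n_cols x periods`,
#'   values in \[-1, 1\]), `ndvi_period_start` (day-of-year each period
#'   starts), and `covariate_groups` mapping each model covariate to
#'   anthropogenic / habitat / productivity.
#' @details If a distance layer has no source cells (e.g. an all-forest
#'   landscape has no residential cells), the layer saturates at the landscape
#'   diagonal — finite by construction, and documented as "farther than
#'   anything on the map".
#' @examples
#' ls <- make_landscape(n_rows = 40, n_cols = 40, seed = 1)
#' table(landcover_class(ls))
#' @export
make_landscape <- function(n_rows = 240, n_cols = 240, cell_size = 250,
                           origin = c(0, 0),
                           prop = c(forest = 0.42, herbaceous = 0.25,
                                    crops = 0.10, residential = 0.03,
                                    other = 0.20),
                           patch_km = 1.2, n_roads = 12,
                           n_ndvi_periods = 46,
                           ndvi_seasonal_amplitude = 0.25,
                           seed = 1L) {
  if (n_rows < 1 || n_cols < 1) {
    stop("degenerate geometry: landscape must have at least one cell")
  }
  if (!setequal(names(prop), LANDCOVER_CLASSES)) {
    stop("`prop` must name all five landcover classes: ",
         paste(LANDCOVER_CLASSES, collapse = ", "))
  }
  if (n_ndvi_periods < 1) stop("need at least one NDVI period")
  prop <- prop[LANDCOVER_CLASSES] / sum(prop)

  set.seed(seed)
  width <- n_cols * cell_size
  height <- n_rows * cell_size
  xc <- origin[1] + (seq_len(n_cols) - 0.5) * cell_size
  yc <- origin[2] + (seq_len(n_rows) - 0.5) * cell_size

  # landcover: quantile bands of a smooth terrain-position field, ordered
  # residential / crops (valley floor) -> herbaceous -> other -> forest;
  # exact class proportions, patch size set by the field wavelength
  field <- .smooth_field(xc, yc, seed = seed + 17L, mean = 0, sd = 1,
                         n_waves = 40, wavelength_m = patch_km * 1000)
  band_order <- c("residential", "crops", "herbaceous", "other", "forest")
  cum <- cumsum(prop[band_order])
  n_cells <- n_rows * n_cols
  q <- (rank(as.vector(field), ties.method = "first") - 0.5) / n_cells
  band <- findInterval(q, cum) + 1L  # 1..5 in band_order
  lc <- matrix(match(band_order[band], LANDCOVER_CLASSES), n_rows, n_cols)
  attr(lc, "levels") <- LANDCOVER_CLASSES

  # roads: straight transects; cells within ~0.6 cell of the line are road
  road <- matrix(FALSE, n_rows, n_cols)
  if (n_roads > 0) {
    ang <- stats::runif(n_roads, 0, pi)
    px <- stats::runif(n_roads, origin[1] + 0.15 * width,
                       origin[1] + 0.85 * width)
    py <- stats::runif(n_roads, origin[2] + 0.15 * height,
                       origin[2] + 0.85 * height)
    X <- matrix(rep(xc, each = n_rows), n_rows, n_cols)
    Y <- matrix(rep(yc, times = n_cols), n_rows, n_cols)
    for (r in seq_len(n_roads)) {
      # distance from cell centers to the infinite line through (px,py)
      d <- abs(-sin(ang[r]) * (X - px[r]) + cos(ang[r]) * (Y - py[r]))
      road <- road | (d <= 0.6 * cell_size)
    }
  }

  dist_development <- .distance_layer(which(lc == which(LANDCOVER_CLASSES ==
                                                          "residential")),
                                      n_rows, n_cols, xc, yc)
  dist_roads <- .distance_layer(which(road), n_rows, n_cols, xc, yc)

  # NDVI: smooth spatial base + amplitude fields, seasonal cosine peaking
  # near day 200, clipped to the physical [-1, 1] range
  base <- .smooth_field(xc, yc, seed = seed + 101L, mean = 0.40, sd = 0.18,
                        n_waves = 40, wavelength_m = patch_km * 1500)
  amp <- .smooth_field(xc, yc, seed = seed + 202L,
                       mean = ndvi_seasonal_amplitude, sd = 0.05,
                       n_waves = 40, wavelength_m = patch_km * 1500)
  amp <- pmax(amp, 0.02)
  period_start <- (seq_len(n_ndvi_periods) - 1) * 8 + 1
  ndvi <- array(0, dim = c(n_rows, n_cols, n_ndvi_periods))
  for (p in seq_len(n_ndvi_periods)) {
    doy <- period_start[p] + 3.5
    s <- cos(2 * pi * (doy - 200) / 365)
    ndvi[, , p] <- pmin(1, pmax(-1, base + amp * s))
  }

  structure(list(
    origin = origin, cell_size = cell_size,
    n_rows = n_rows, n_cols = n_cols,
    landcover = lc, road = road,
    dist_development = dist_development,
    dist_roads = dist_roads,
    ndvi = ndvi, ndvi_period_start = period_start,
    covariate_groups = COVARIATE_GROUPS,
    seed = seed
  ), class = "covariate_stack")
}

# Euclidean distance (m) from every cell center to the nearest source cell
# center; brute-force running minimum over sources (grids here are small).
.distance_layer <- function(source_idx, n_rows, n_cols, xc, yc) {
  if (length(source_idx) == 0) {
    # no sources anywhere: saturate at the landscape diagonal (finite)
    diag_m <- sqrt(diff(range(xc))^2 + diff(range(yc))^2) + 1
    return(matrix(diag_m, n_rows, n_cols))
  }
  sr <- ((source_idx - 1) %% n_rows) + 1
  sc <- ((source_idx - 1) %/% n_rows) + 1
  best <- matrix(Inf, n_rows, n_cols)
  for (k in seq_along(source_idx)) {
    d2 <- outer((yc - yc[sr[k]])^2, (xc - xc[sc[k]])^2, "+")
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# smooth random surface: sum of random-phase cosine waves; wavelength_m
# controls the characteristic patch scale (defaults to a third of the extent)
.smooth_field <- function(xc, yc, seed, mean = 0, sd = 1, n_waves = 6,
                          wavelength_m = NULL) {
  set.seed(seed)
  L <- max(diff(range(xc)), diff(range(yc)), 1)
  if (is.null(wavelength_m)) wavelength_m <- L / 3
  f <- matrix(0, length(yc), length(xc))
  for (w in seq_len(n_waves)) {
    wl <- stats::runif(1, wavelength_m, 3 * wavelength_m)
    th <- stats::runif(1, 0, pi)
    fx <- cos(th) / wl
    fy <- sin(th) / wl
    ph <- stats::runif(2, 0, 2 * pi)
    a <- stats::rnorm(1)
    f <- f + a * outer(cos(2 * pi * fy * yc + ph[2]),
                       cos(2 * pi * fx * xc + ph[1]))
  }
  mean + sd * (f - base::mean(f)) / stats::sd(as.vector(f))
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat("<covariate_stack> ", x$n_rows, "x", x$n_cols, " cells @ ",
      x$cell_size, " m (", round(x$n_cols * x$cell_size / 1000, 1), " x ",
      round(x$n_rows * x$cell_size / 1000, 1), " km)\n", sep = "")
  tab <- table(factor(attr(x$landcover, "levels")[x$landcover],
                      levels = attr(x$landcover, "levels")))
  cat("  landcover: ",
      paste(names(tab), sprintf("%.1f%%", 100 * tab / sum(tab)),
            collapse = ", "), "\n", sep = "")
  cat("  NDVI periods: ", dim(x$ndvi)[3], " (8-day)\n", sep = "")
  invisible(x)
}

#' Landscape cell lookup
#'
#' Maps projected coordinates to grid cells of a [make_landscape()] stack.
#' Points outside the grid map to `NA`.
#'
#' @param stack a `covariate_stack`.
#' @param x,y coordinates (m).
#' @return integer matrix with columns `row`, `col`.
#' @export
xy_to_cell <- function(stack, x, y) {
  col <- floor((x - stack$origin[1]) / stack$cell_size) + 1
  row <- floor((y - stack$origin[2]) / stack$cell_size) + 1
  bad <- col < 1 | col > stack$n_cols | row < 1 | row > stack$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname xy_to_cell
#' @export
landcover_class <- function(stack, x = NULL, y = NULL) {
  lv <- attr(stack$landcover, "levels")
  if (is.null(x)) return(factor(lv[stack$landcover], levels = lv))
  rc <- xy_to_cell(stack, x, y)
  factor(lv[stack$landcover[rc]], levels = lv)
}

# index of the 8-day NDVI period containing a study day (floor; day-of-year
# recycles annually)
ndvi_period <- function(stack, day) {
  doy <- ((floor(day) - 1) %% 365) + 1
  pmin(dim(stack$ndvi)[3], ((doy - 1) %/% 8) + 1)
}

#' Extract model covariates at points
#'
#' Looks up the containing cell (no interpolation) for each point and returns
#' the design covariates: landcover indicators against the forest reference,
#' distances in meters, and NDVI matched to the 8-day period containing each
#' point's date.
#'
#' @param stack a `covariate_stack`.
#' @param x,y coordinates (m).
#' @param day study day of each point (recycled if length 1).
#' @return data.frame with `landcover`, `crops`, `herbaceous`, `other`,
#'   `dist_development`, `dist_roads`, `ndvi`. Out-of-bounds points yield NA
#'   rows.
#' @export
extract_covariates <- function(stack, x, y, day) {
  n <- length(x)
  day <- rep_len(day, n)
  rc <- xy_to_cell(stack, x, y)
  idx <- rc[, "row"] + (rc[, "col"] - 1) * stack$n_rows
  lv <- attr(stack$landcover, "levels")
  lc <- lv[stack$landcover[idx]]
  per <- ndvi_period(stack, day)
  nd <- stack$ndvi[cbind(rc[, "row"], rc[, "col"], per)]
  data.frame(
    landcover = factor(lc, levels = lv),
    crops = as.numeric(lc == "crops"),
    herbaceous = as.numeric(lc == "herbaceous"),
    other = as.numeric(lc %in% c("other", "residential")),
    dist_development = stack$dist_development[idx],
    dist_roads = stack$dist_roads[idx],
    ndvi = nd
  )
}

# linear predictor covariates as used in both the simulator's selection
# weights and the fitted models (natural scale: indicators, ln(d+1), NDVI)
design_matrix_natural <- function(cov) {
  cbind(
    crops = cov$crops,
    herbaceous = cov$herbaceous,
    other = cov$other,
    ln_dist_development = log1p(cov$dist_development),
    ln_dist_roads = log1p(cov$dist_roads),
    ndvi = cov$ndvi
  )
}

#' Export a covariate stack as plain-text rasters
#'
#' Writes each static layer as an ESRI ASCII grid (`.asc`) plus a JSON
#' sidecar with the covariate-group map; NDVI periods are written as
#' individual grids.
#'
#' @param stack a `covariate_stack`.
#' @param dir output directory (created if needed).
#' @param ndvi_periods which NDVI periods to export (default: none).
#' @return invisibly, the paths written.
#' @export
write_landscape_asc <- function(stack, dir, ndvi_periods = integer(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(mat, name) {
    p <- file.path(dir, paste0(name, ".asc"))
    hdr <- c(
      paste("ncols", stack$n_cols), paste("nrows", stack$n_rows),
      paste("xllcorner", stack$origin[1]), paste("yllcorner", stack$origin[2]),
      paste("cellsize", stack$cell_size), "NODATA_value -9999"
    )
    # .asc rows run north to south: flip the row order
    body <- apply(mat[rev(seq_len(stack$n_rows)), , drop = FALSE], 1,
                  paste, collapse = " ")
    writeLines(c(hdr, body), p)
    p
  }
  paths <- c(paths, wr(stack$landcover, "landcover"),
             wr(round(stack$dist_development, 1), "dist_development"),
             wr(round(stack$dist_roads, 1), "dist_roads"))
  for (p in ndvi_periods) {
    paths <- c(paths, wr(round(stack$ndvi[, , p], 4),
                         sprintf("ndvi_period_%02d", p)))
  }
  gj <- file.path(dir, "covariate_groups.json")
  jsonlite::write_json(as.list(stack$covariate_groups), gj,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, gj))
}
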