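#' Build a true selection-coefficient grid
#'
#' Constructs the herd x season x strategy grid of true selection
#' coefficients used to drive the trajectory simulator and to benchmark
#' recovery. Coefficients are additive: a shared baseline plus herd, season,
#' and strategy offsets whose magnitudes set the planted hierarchy of
#' differentiation. Offsets are weighted per covariate group so that
#' anthropogenic covariates carry the most differentiation and productivity
#' (NDVI) the least, the structure typical of partially migratory ungulate
#' systems; `anthropogenic_only = TRUE` confines all differentiation to the
#' anthropogenic covariates.
#'
#' Coefficients are on the natural covariate scale: per landcover indicator,
#' per unit `ln(distance m + 1)`, per unit NDVI.
#'
#' @param herds character vector of herd names.
#' @param herd_scale,season_scale,strategy_scale offset magnitudes; the
#'   defaults plant `herd > season > strategy` differentiation.
#' @param anthropogenic_only confine offsets to the anthropogenic covariates.
#' @param style `"hierarchical"` (additive offsets, the study-emulation
#'   default) or `"distinct"`: every herd-season-strategy model gets a
#'   different permutation of six well-separated values in \[-1, 1\], the
#'   design used for coefficient-recovery benchmarks.
#' @return data.frame with columns `herd, season, strategy, covariate, beta`.
#' @export
make_beta_grid <- function(herds = c("A", "B", "C", "D"),
                           herd_scale = 0.5, season_scale = 0.3,
                           strategy_scale = 0.12,
                           anthropogenic_only = FALSE,
                           style = c("hierarchical", "distinct")) {
  style <- match.arg(style)
  covs <- RSF_COVARIATES
  if (style == "distinct") {
    vals <- c(-1, -0.6, -0.2, 0.2, 0.6, 1)
    grid <- expand.grid(herd = herds, season = c("winter", "summer"),
                        strategy = c("migrant", "resident"),
                        stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      shift <- (i - 1) %% 6
      flip <- if (((i - 1) %/% 6) %% 2 == 1) -1 else 1
      data.frame(herd = grid$herd[i], season = grid$season[i],
                 strategy = grid$strategy[i], covariate = covs,
                 beta = flip * vals[((seq_along(covs) - 1 + shift) %% 6) + 1])
    }))
    rownames(out) <- NULL
    return(out)
  }
  base <- c(crops = 0.35, herbaceous = 0.30, other = -0.20,
            ln_dist_development = 0.40, ln_dist_roads = 0.25, ndvi = 0.10)
  # per-covariate receptiveness to offsets: anthropogenic most, NDVI least
  w <- c(crops = 1, herbaceous = 0.6, other = 0.6,
         ln_dist_development = 1, ln_dist_roads = 1, ndvi = 0.15)
  if (anthropogenic_only) {
    w[c("herbaceous", "other", "ndvi")] <- 0
  }
  # alternate offset direction across covariates so levels differ in pattern,
  # not by a common shift (consistency is translation invariant)
  dir <- c(crops = 1, herbaceous = -1, other = 1,
           ln_dist_development = -1, ln_dist_roads = 1, ndvi = -1)
  H <- length(herds)
  u <- if (H > 1) (seq_len(H) - (H + 1) / 2) / ((H - 1) / 2) else 0
  grid <- expand.grid(herd = herds, season = c("winter", "summer"),
                      strategy = c("migrant", "resident"),
                      covariate = covs, stringsAsFactors = FALSE)
  ndvi_summer <- if (anthropogenic_only) 0 else 0.35
  grid$beta <- mapply(function(h, s, m, k) {
    b <- base[k] +
      herd_scale * u[match(h, herds)] * w[k] * dir[k] +
      season_scale * (if (s == "summer") 0.5 else -0.5) * w[k] * dir[k] *
        (if (match(k, covs) %% 2 == 0) -1 else 1) +
      strategy_scale * (if (m == "migrant") 0.5 else -0.5) * w[k] * dir[k]
    if (k == "ndvi" && s == "summer") b <- b + ndvi_summer
    unname(b)
  }, grid$herd, grid$season, grid$strategy, grid$covariate)
  grid
}

#' @rdname make_beta_grid
#' @param beta_grid a coefficient grid from `make_beta_grid()`.
#' @param herd,season,strategy the model whose true coefficients to return.
#' @export
get_beta <- function(beta_grid, herd, season, strategy) {
  sel <- beta_grid$herd == herd & beta_grid$season == season &
    beta_grid$strategy == strategy
  b <- beta_grid$beta[sel]
  names(b) <- beta_grid$covariate[sel]
  b[RSF_COVARIATES]
}

#' Define a simulation scenario
#'
#' A scenario bundles the population design (herds, sample sizes, migrant
#' proportions), GPS sampling regime, migration phenology, movement-kernel
#' parameters, and the true coefficient grid. The default emulates a
#' multi-herd partially migratory elk study: four herds of 20 animal-years
#' with migrant proportions spanning 25-100%, fixes every 2 h over 342 days
#' starting from a mid-winter capture, spring migration centered near day
#' 150 and autumn return near day 280, and seasonal ranges roughly 40 km
#' apart for migrants.
#'
#' @param herds data.frame with columns `herd`, `n`, `migrant_prop`.
#' @param fix_interval_h hours between fixes (1, 2, or 4).
#' @param span_days tracking duration per animal-year.
#' @param start_day_range study-day window for the first fix (mid-winter
#'   captures).
#' @param spring_mid,autumn_mid mean study day of the spring / autumn
#'   migration midpoints.
#' @param mid_sd between-animal SD of migration midpoints (days).
#' @param window_days mean 5-95% duration of a migratory transition (days).
#' @param sep_km mean separation between migrant seasonal range centers.
#' @param range_radius radius (m) of the circular seasonal range around
#'   each center; positions are proposed uniformly within it, giving a
#'   roughly 28 km^2 range at the 3 km default.
#' @param n_candidates candidate positions per fix evaluated by the
#'   selection thinning.
#' @param beta_grid true coefficient grid (see [make_beta_grid()]); `NULL`
#'   for the default grid over the scenario's herds.
#' @param landscape optional pre-built [make_landscape()] stack.
#' @param landscape_args arguments for [make_landscape()] when `landscape`
#'   is `NULL`.
#' @return a list of class `rsf_scenario`.
#' @export
make_scenario <- function(herds = data.frame(
                            herd = c("A", "B", "C", "D"),
                            n = c(20, 20, 20, 20),
                            migrant_prop = c(1, 0.75, 0.5, 0.25)),
                          fix_interval_h = 2, span_days = 342,
                          start_day_range = c(5, 60),
                          spring_mid = 150, autumn_mid = 280, mid_sd = 8,
                          window_days = 20, sep_km = 40,
                          range_radius = 3000, n_candidates = 30,
                          beta_grid = NULL, landscape = NULL,
                          landscape_args = list()) {
  if (!is.data.frame(herds)) {
    # YAML configs: lists coerce; YAML 1.1 reads a bare key `n` as FALSE
    names(herds)[names(herds) %in% c("FALSE", "F")] <- "n"
    herds <- as.data.frame(herds)
  }
  stopifnot(all(c("herd", "n", "migrant_prop") %in% names(herds)))
  if (any(herds$n <= 0)) stop("herd sample sizes must be positive")
  if (any(herds$migrant_prop < 0 | herds$migrant_prop > 1)) {
    stop("migrant proportions must lie in [0, 1]")
  }
  if (!fix_interval_h %in% c(1, 2, 4)) {
    stop("fix_interval_h must be 1, 2, or 4")
  }
  if (is.null(beta_grid)) beta_grid <- make_beta_grid(herds$herd)
  structure(list(
    herds = herds, fix_interval_h = fix_interval_h, span_days = span_days,
    start_day_range = start_day_range, spring_mid = spring_mid,
    autumn_mid = autumn_mid, mid_sd = mid_sd, window_days = window_days,
    sep_km = sep_km, range_radius = range_radius,
    n_candidates = n_candidates, beta_grid = beta_grid,
    landscape = landscape, landscape_args = landscape_args
  ), class = "rsf_scenario")
}

#' @export
print.rsf_scenario <- function(x, ...) {
  cat("<rsf_scenario> ", sum(x$herds$n), " animal-years in ",
      nrow(x$herds), " herds; fixes every ", x$fix_interval_h,
      " h over ", x$span_days, " d\n", sep = "")
  print(x$herds, row.names = FALSE)
  invisible(x)
}

# ln(19): a logistic covers 5% -> 95% of its rise over 2*phi*ln(19)
LN19 <- log(19)

# Draw the per-animal truth rows for a scenario. Migration departure and
# arrival are recorded on the NSD scale: the days the squared displacement of
# the true center path crosses 5% and 95% of its plateau, the same definition
# the classifier applies to fitted curves.
draw_truth <- function(scenario, stack, seed) {
  set.seed(seed)
  sc <- scenario
  extent <- min(stack$n_cols, stack$n_rows) * stack$cell_size
  margin <- min(2 * sc$range_radius, 0.2 * extent)
  xlim <- c(stack$origin[1] + margin,
            stack$origin[1] + stack$n_cols * stack$cell_size - margin)
  ylim <- c(stack$origin[2] + margin,
            stack$origin[2] + stack$n_rows * stack$cell_size - margin)
  rows <- list()
  for (h in seq_len(nrow(sc$herds))) {
    herd <- sc$herds$herd[h]
    n <- sc$herds$n[h]
    n_mig <- round(sc$herds$migrant_prop[h] * n)
    # herd-level winter centroid and a feasible summer centroid sep_km away
    sep <- sc$sep_km * 1000
    tries <- 0
    repeat {
      wc <- c(stats::runif(1, xlim[1], xlim[2]),
              stats::runif(1, ylim[1], ylim[2]))
      ang <- stats::runif(1, 0, 2 * pi)
      smc <- wc + sep * c(cos(ang), sin(ang))
      if (smc[1] > xlim[1] && smc[1] < xlim[2] &&
          smc[2] > ylim[1] && smc[2] < ylim[2]) break
      tries <- tries + 1
      if (tries %% 50 == 0 && sep > 10000) sep <- 0.9 * sep
    }
    for (i in seq_len(n)) {
      migrant <- i <= n_mig
      c1 <- pmin(pmax(wc + stats::rnorm(2, 0, 5000), xlim[1]), xlim[2])
      c2 <- if (migrant) {
        pmin(pmax(smc + stats::rnorm(2, 0, 5000), xlim[1]), xlim[2])
      } else c(NA_real_, NA_real_)
      theta1 <- stats::rnorm(1, sc$spring_mid, sc$mid_sd)
      theta2 <- stats::rnorm(1, sc$autumn_mid, sc$mid_sd)
      win <- pmax(8, stats::rnorm(2, sc$window_days, sc$window_days / 5))
      phi1 <- win[1] / (2 * LN19)
      phi2 <- win[2] / (2 * LN19)
      start <- stats::runif(1, sc$start_day_range[1], sc$start_day_range[2])
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = sprintf("%s%02d", herd, i), herd = herd,
        strategy = if (migrant) "migrant" else "resident",
        start_day = start, span_days = sc$span_days,
        fix_interval_h = sc$fix_interval_h,
        c1x = c1[1], c1y = c1[2], c2x = c2[1], c2y = c2[2],
        theta1 = theta1, phi1 = phi1, theta2 = theta2, phi2 = phi2,
        # NSD-scale 5%/95% transition window: displacement is logistic, so
        # NSD crosses 5%/95% of its plateau at logit(sqrt(.)) multiples on
        # the outbound rise and mirrored on the return fall
        dep1 = theta1 + phi1 * .logit(sqrt(0.05)),
        arr1 = theta1 + phi1 * .logit(sqrt(0.95)),
        dep2 = theta2 + phi2 * .logit(1 - sqrt(0.95)),
        arr2 = theta2 + phi2 * .logit(1 - sqrt(0.05)),
        sep_km = if (migrant) sqrt(sum((c2 - c1)^2)) / 1000 else 0
      )
    }
  }
  do.call(rbind, rows)
}

.logit <- function(p) log(p / (1 - p))

#' Simulate one GPS trajectory
#'
#' Range-residency with third-order selection imposed by candidate-step
#' thinning: at each fix interval, candidate positions are proposed
#' uniformly within the circular range around the current range center and
#' one is kept with probability proportional to `exp(beta' x)` evaluated on
#' the candidate's covariates, so the used distribution is exactly the
#' exponential selection form over a uniform within-range availability —
#' the model the downstream estimator assumes. Migrant centers relocate
#' between the two seasonal centers along a logistic displacement curve,
#' producing the double-sigmoid NSD signature. Selection remains
#' approximate in magnitude (a finite candidate set and the fitted 95%
#' isopleth trimming low-use area both shrink coefficients slightly), so
#' recovery checks use tolerance bands.
#'
#' @param truth one row of the truth table from [simulate_population()] /
#'   `draw_truth`.
#' @param stack a `covariate_stack`.
#' @param beta_grid true coefficient grid (natural scale).
#' @param scenario the `rsf_scenario` providing kernel parameters.
#' @param seed integer seed.
#' @return data.frame with `animal_id, herd, timestamp, x, y`.
#' @export
simulate_trajectory <- function(truth, stack, beta_grid, scenario, seed) {
  set.seed(seed)
  sc <- scenario
  xmin <- stack$origin[1] + 0.5 * stack$cell_size
  xmax <- stack$origin[1] + (stack$n_cols - 0.5) * stack$cell_size
  ymin <- stack$origin[2] + 0.5 * stack$cell_size
  ymax <- stack$origin[2] + (stack$n_rows - 0.5) * stack$cell_size
  if (truth$c1x < xmin || truth$c1x > xmax ||
      truth$c1y < ymin || truth$c1y > ymax) {
    stop("animal range center lies outside the landscape")
  }
  dt <- truth$fix_interval_h / 24
  n <- floor(truth$span_days / dt) + 1
  t_day <- truth$start_day + (seq_len(n) - 1) * dt

  migrant <- truth$strategy == "migrant"
  if (migrant) {
    g1 <- stats::plogis((t_day - truth$theta1) / truth$phi1)
    g2 <- stats::plogis((t_day - truth$theta2) / truth$phi2)
    w <- g1 - g2
    cx <- truth$c1x + (truth$c2x - truth$c1x) * w
    cy <- truth$c1y + (truth$c2y - truth$c1y) * w
  } else {
    cx <- rep(truth$c1x, n)
    cy <- rep(truth$c1y, n)
  }
  season <- ifelse(t_day > truth$theta1 & t_day < truth$theta2,
                   "summer", "winter")
  b_w <- get_beta(beta_grid, truth$herd, "winter", truth$strategy)
  b_s <- get_beta(beta_grid, truth$herd, "summer", truth$strategy)

  R <- sc$range_radius
  no_selection <- all(b_w == 0) && all(b_s == 0)
  K <- if (no_selection) 1L else sc$n_candidates
  # candidate positions: uniform over the disc of radius R around the
  # (possibly migrating) center; kept within landscape bounds
  rad <- matrix(R * sqrt(stats::runif(n * K)), n, K)
  ang <- matrix(stats::runif(n * K, 0, 2 * pi), n, K)
  pick_u <- stats::runif(n)
  per <- ndvi_period(stack, t_day)
  x <- numeric(n); y <- numeric(n)
  inv_cs <- 1 / stack$cell_size
  for (i in seq_len(n)) {
    px <- pmin(pmax(cx[i] + rad[i, ] * cos(ang[i, ]), xmin), xmax)
    py <- pmin(pmax(cy[i] + rad[i, ] * sin(ang[i, ]), ymin), ymax)
    if (no_selection) {
      x[i] <- px[1]
      y[i] <- py[1]
      next
    }
    col <- floor((px - stack$origin[1]) * inv_cs) + 1
    row <- floor((py - stack$origin[2]) * inv_cs) + 1
    idx <- row + (col - 1) * stack$n_rows
    lc <- stack$landcover[idx]
    b <- if (season[i] == "summer") b_s else b_w
    eta <- b[["crops"]] * (lc == 3L) +
      b[["herbaceous"]] * (lc == 2L) +
      b[["other"]] * (lc == 5L | lc == 4L) +
      b[["ln_dist_development"]] * log1p(stack$dist_development[idx]) +
      b[["ln_dist_roads"]] * log1p(stack$dist_roads[idx]) +
      b[["ndvi"]] * stack$ndvi[idx + (per[i] - 1) *
                                 stack$n_rows * stack$n_cols]
    wgt <- exp(eta - max(eta))
    j <- min(findInterval(pick_u[i] * sum(wgt), cumsum(wgt)) + 1, K)
    x[i] <- px[j]
    y[i] <- py[j]
  }
  data.frame(
    animal_id = truth$animal_id, herd = truth$herd,
    timestamp = study_time(t_day), x = x, y = y
  )
}

#' Simulate a multi-herd population
#'
#' Draws the per-animal ground truth for a scenario (strategies, range
#' centers, migration timing) and simulates every trajectory over a shared
#' landscape. Fully reproducible: the seed fans out deterministically to the
#' landscape, the truth draw, and each animal.
#'
#' @param scenario an `rsf_scenario` from [make_scenario()].
#' @param seed integer seed.
#' @return list of class `rsf_population` with `fixes` (one data.frame of all
#'   GPS fixes), `truth` (per-animal truth table), `beta` (true coefficient
#'   grid), and `stack` (the landscape).
#' @export
simulate_population <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "rsf_scenario"))
  stack <- scenario$landscape
  if (is.null(stack)) {
    stack <- do.call(make_landscape,
                     c(scenario$landscape_args,
                       list(seed = split_seed(seed, "landscape"))))
  }
  truth <- draw_truth(scenario, stack, split_seed(seed, "truth"))
  fixes <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    fixes[[i]] <- simulate_trajectory(truth[i, ], stack, scenario$beta_grid,
                                      scenario, split_seed(seed, 1000 + i))
  }
  structure(list(
    fixes = do.call(rbind, fixes), truth = truth,
    beta = scenario$beta_grid, stack = stack, seed = seed
  ), class = "rsf_population")
}

#' @export
print.rsf_population <- function(x, ...) {
  cat("<rsf_population> ", nrow(x$truth), " animal-years, ",
      nrow(x$fixes), " fixes (",
      paste(unique(x$truth$herd), collapse = ", "), ")\n", sep = "")
  print(table(x$truth$herd, x$truth$strategy))
  invisible(x)
}
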