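#' Classify the movement strategy of an animal-year
#'
#' Picks the best-supported member of the five-model NSD family by AICc and
#' maps it to a strategy: migrant and mixed-migrant fits to `migrant`,
#' constant fits to `resident`, and single-sigmoid or linear-drift fits
#' (settling dispersal, sustained directional persistence) to `disperser`.
#' Animal-years tracked for five months or less are `excluded`
#' ("insufficient data"), and the call is `ambiguous` when the top two
#' models are within `ambiguity_delta` AICc of each other but imply
#' different strategies.
#'
#' @param scan an `nsd_scan` from [fit_nsd_models()].
#' @param min_months exclusion threshold: tracking spans of at most this
#'   many months (30.44 d each) are excluded.
#' @param ambiguity_delta AICc margin below which competing strategies make
#'   the call ambiguous.
#' @param min_delta ecological amplitude threshold (km^2 of NSD): a
#'   sigmoid or drift fit whose displacement amplitude stays below this is
#'   residency (animals that merely commute short distances within a
#'   range), not migration or dispersal. The default, 25 km^2, treats
#'   range shifts under 5 km as within-range movement.
#' @return one-row data.frame (a strategy call): `animal_id, strategy,
#'   model_class, delta, theta, phi, delta2, theta2, phi2, c, beta_nomad,
#'   aicc_best, aicc_margin, dep1, arr1, dep2, arr2, reason` with dates in
#'   days since first fix.
#' @export
classify_strategy <- function(scan, min_months = 5, ambiguity_delta = 2,
                              min_delta = 25) {
  span <- attr(scan, "span_days")
  id <- attr(scan, "animal_id")
  out <- data.frame(
    animal_id = id, strategy = NA_character_, model_class = NA_character_,
    delta = NA_real_, theta = NA_real_, phi = NA_real_, delta2 = NA_real_,
    theta2 = NA_real_, phi2 = NA_real_, c = NA_real_,
    beta_nomad = NA_real_, aicc_best = NA_real_, aicc_margin = NA_real_,
    dep1 = NA_real_, arr1 = NA_real_, dep2 = NA_real_, arr2 = NA_real_,
    reason = ""
  )
  if (span <= min_months * 30.44) {
    out$strategy <- "excluded"
    out$reason <- "insufficient data"
    return(out)
  }
  fits <- unclass(scan)
  conv <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(conv) == 0) {
    out$strategy <- "excluded"
    out$reason <- "no NSD model converged"
    return(out)
  }
  aicc <- vapply(conv, function(f) f$aicc, numeric(1))
  ord <- order(aicc)
  best <- conv[[ord[1]]]
  # strategy implied by a fit: model class, demoted to residency when the
  # fitted displacement amplitude is ecologically negligible
  implied <- function(f) {
    amp <- switch(f$model,
      resident = 0,
      nomad = abs(f$coef[["beta"]]) * span,
      disperser = f$coef[["delta"]],
      migrant = f$coef[["delta"]],
      mixed_migrant = max(f$coef[["delta"]], f$coef[["delta2"]])
    )
    if (amp < min_delta) return("resident")
    switch(f$model, resident = "resident", nomad = "disperser",
           disperser = "disperser", migrant = "migrant",
           mixed_migrant = "migrant")
  }
  out$model_class <- best$model
  out$aicc_best <- best$aicc
  strategy <- implied(best)
  if (length(ord) > 1) {
    second <- conv[[ord[2]]]
    out$aicc_margin <- second$aicc - best$aicc
    if (out$aicc_margin < ambiguity_delta &&
        implied(second) != strategy) {
      out$strategy <- "ambiguous"
      out$reason <- sprintf("dAICc %.2f between %s and %s",
                            out$aicc_margin, best$model, second$model)
      return(out)
    }
  }
  out$strategy <- strategy
  cf <- best$coef
  for (nm in intersect(names(cf),
                       c("delta", "theta", "phi", "delta2", "theta2",
                         "phi2", "c"))) {
    out[[nm]] <- cf[[nm]]
  }
  if ("beta" %in% names(cf)) out$beta_nomad <- cf[["beta"]]
  if (strategy == "migrant") {
    md <- migration_dates(best)
    out$dep1 <- md$departure[1]; out$arr1 <- md$arrival[1]
    out$dep2 <- md$departure[2]; out$arr2 <- md$arrival[2]
  }
  out
}

#' Classify every animal-year in a fix table
#'
#' Runs [compute_nsd()], [fit_nsd_models()] and [classify_strategy()] per
#' animal and attaches herd labels and study-day timing (migration dates
#' shifted from the days-since-first-fix scale to the study-day axis).
#'
#' @param fixes fix data.frame (`animal_id, herd, timestamp, x, y`).
#' @inheritParams classify_strategy
#' @return data.frame of class `strategy_calls`, one row per animal-year.
#' @export
classify_population <- function(fixes, min_months = 5, ambiguity_delta = 2,
                                min_delta = 25) {
  ids <- unique(fixes$animal_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    traj <- fixes[fixes$animal_id == ids[i], ]
    series <- compute_nsd(traj)
    call <- classify_strategy(fit_nsd_models(series),
                              min_months = min_months,
                              ambiguity_delta = ambiguity_delta,
                              min_delta = min_delta)
    call$herd <- as.character(traj$herd[1])
    start <- study_day(min(traj$timestamp))
    call$start_day <- start
    call$end_day <- study_day(max(traj$timestamp))
    for (col in c("dep1", "arr1", "dep2", "arr2")) {
      call[[col]] <- call[[col]] + start
    }
    rows[[i]] <- call
  }
  out <- do.call(rbind, rows)
  class(out) <- c("strategy_calls", "data.frame")
  out
}

#' @export
print.strategy_calls <- function(x, ...) {
  cat("<strategy_calls> ", nrow(x), " animal-years\n", sep = "")
  print(table(x$herd, x$strategy))
  invisible(x)
}

#' Herd-level median migration dates
#'
#' Elementwise medians of the migrant departure/arrival dates within each
#' herd, used to cut resident fix series into the same seasonal windows as
#' their migratory herd-mates. Herds without any classified migrant are
#' omitted with a warning.
#'
#' @param calls a `strategy_calls` table with study-day dates.
#' @return data.frame (season table): `herd, dep1, arr1, dep2, arr2,
#'   n_migrants` (study days).
#' @export
herd_median_dates <- function(calls) {
  herds <- unique(calls$herd)
  rows <- list()
  for (h in herds) {
    mig <- calls[calls$herd == h & calls$strategy == "migrant" &
                   !is.na(calls$dep1), ]
    if (nrow(mig) == 0) {
      warning("herd ", h, " has no classified migrants; no season entry")
      next
    }
    rows[[h]] <- data.frame(
      herd = h,
      dep1 = stats::median(mig$dep1), arr1 = stats::median(mig$arr1),
      dep2 = stats::median(mig$dep2), arr2 = stats::median(mig$arr2),
      n_migrants = nrow(mig)
    )
  }
  if (length(rows) == 0) stop("no herd has any classified migrant")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label fixes with seasonal ranges
#'
#' Applies the three-range delineation: for migrants, seasons are bounded
#' by the animal's own fitted departure/arrival dates and transit fixes
#' (between a departure and the matching arrival) belong to neither season;
#' for residents, the herd's median migration dates cut the year into the
#' same windows. Animals first located after their spring departure lack a
#' first winter and fall back to a summer-winter(-summer) sequence. Ranges
#' with too little data (fewer than `min_fixes` fixes or spanning fewer
#' than `min_days` days) are unusable; an animal with fewer than two usable
#' ranges is flagged `unclear` and should be dropped from selection
#' modelling.
#'
#' @param traj one animal's fixes.
#' @param call its row from a `strategy_calls` table (study-day dates).
#' @param season_table herd median dates from [herd_median_dates()]
#'   (required for residents).
#' @param min_days,min_fixes usability thresholds per seasonal range.
#' @return `traj` with added `day` (study day), `season`
#'   (`winter`/`summer`, `NA` in transit), `range_id` (e.g. `winter1`), and
#'   `year`; attributes `usable_ranges` (character vector) and `unclear`
#'   (logical).
#' @export
assign_seasons <- function(traj, call, season_table = NULL,
                           min_days = 30, min_fixes = 50) {
  if (!call$strategy %in% c("migrant", "resident")) {
    stop("seasonal ranges are delineated only for migrant or resident calls")
  }
  if (call$strategy == "migrant") {
    d <- c(call$dep1, call$arr1, call$dep2, call$arr2)
  } else {
    if (is.null(season_table) || !call$herd %in% season_table$herd) {
      stop("no season-table entry for herd ", call$herd,
           "; cannot cut resident seasons")
    }
    st <- season_table[season_table$herd == call$herd, ]
    d <- c(st$dep1, st$arr1, st$dep2, st$arr2)
  }
  day <- study_day(traj$timestamp)
  range_id <- rep(NA_character_, nrow(traj))
  range_id[day < d[1]] <- "winter1"
  range_id[day > d[2] & day < d[3]] <- "summer1"
  range_id[day > d[4]] <- "winter2"
  season <- c(winter1 = "winter", summer1 = "summer",
              winter2 = "winter")[range_id]
  year <- c(winter1 = 1L, summer1 = 1L, winter2 = 2L)[range_id]

  traj$day <- day
  traj$season <- unname(season)
  traj$range_id <- range_id
  traj$year <- unname(year)

  usable <- character(0)
  for (rid in c("winter1", "summer1", "winter2")) {
    sel <- !is.na(range_id) & range_id == rid
    if (sum(sel) >= min_fixes && diff(range(day[sel])) >= min_days) {
      usable <- c(usable, rid)
    }
  }
  attr(traj, "usable_ranges") <- usable
  attr(traj, "unclear") <- length(usable) < 2
  traj
}
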