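#' @keywords internal
"_PACKAGE"

# Design covariates used throughout: landcover indicators against the forest
# reference, log-distances, and NDVI.
RSF_COVARIATES <- c("crops", "herbaceous", "other",
                    "ln_dist_development", "ln_dist_roads", "ndvi")

COVARIATE_GROUPS <- c(
  crops = "anthropogenic",
  ln_dist_development = "anthropogenic",
  ln_dist_roads = "anthropogenic",
  herbaceous = "habitat",
  other = "habitat",
  ndvi = "productivity"
)

LANDCOVER_CLASSES <- c("forest", "herbaceous", "crops", "residential", "other")

# Study-day axis: days since Jan 1 of the first tracking year (day 1 = Jan 1).
# Keeps dates monotone across the year boundary instead of wrapping at 365.
STUDY_ORIGIN <- "2019-01-01"

#' Convert timestamps to study days
#'
#' Study days count from 1 at 00:00 UTC on January 1 of the study's first
#' year, increasing continuously across year boundaries (so day 400 is early
#' February of year two).
#'
#' @param time `POSIXct` timestamps (UTC).
#' @param origin origin date (`"YYYY-MM-DD"`); defaults to Jan 1 2019.
#' @return numeric study days (fractional).
#' @export
study_day <- function(time, origin = STUDY_ORIGIN) {
  o <- as.POSIXct(paste0(origin, " 00:00:00"), tz = "UTC")
  as.numeric(difftime(time, o, units = "days")) + 1
}

#' @rdname study_day
#' @param day numeric study days.
#' @return `study_time()` returns POSIXct timestamps.
#' @export
study_time <- function(day, origin = STUDY_ORIGIN) {
  o <- as.POSIXct(paste0(origin, " 00:00:00"), tz = "UTC")
  o + (day - 1) * 86400
}

# deterministic fan-out of one global seed into per-stage seeds; keeps values
# inside 32-bit integer range
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  idx <- if (is.character(stage)) {
    sum(utf8ToInt(stage)) %% 1000L
  } else {
    as.integer(stage)
  }
  as.integer((abs(as.numeric(seed)) + 7919 * (idx + 1)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
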