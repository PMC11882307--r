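#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], which can be
#' edited in place or loaded from a YAML file. Stage parameters mirror the
#' standard design: 5-month exclusion threshold, 10,000 available points
#' per animal-season-year, 95% isopleths, VIF threshold 10, and 10,000
#' Monte Carlo draws at `alpha = 0.05`.
#'
#' @param seed global seed; fanned out deterministically to per-stage
#'   seeds.
#' @param out_dir output directory for stage artifacts.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("hierRSF_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    input = list(gps_csv = NULL),   # path to real data; NULL -> simulate
    scenario = list(),              # args for make_scenario()
    stages = list(simulate = TRUE, classify = TRUE, ranges = TRUE,
                  rsf = TRUE, consistency = TRUE),
    classify = list(min_months = 5, ambiguity_delta = 2),
    ranges = list(level = 0.95, min_days = 30, min_fixes = 50),
    rsf = list(n_available = 10000, vif_threshold = 10,
               estimator = "two_stage"),
    consistency = list(B = 10000, alpha = 0.05)
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  modifyList(base, config)
}

#' Validate pipeline inputs
#'
#' Report-only checks of a GPS CSV (schema, parsable timestamps), a
#' covariate stack (shared layer geometry, NDVI range), and their
#' agreement (fix coordinates within the stack, fix dates covered by NDVI
#' periods). Returns a machine-readable issue table; an empty table means
#' a clean fixture.
#'
#' @param gps_csv path to a GPS CSV (optional).
#' @param stack a `covariate_stack` (optional).
#' @param fixes an already-read fix table (optional, alternative to
#'   `gps_csv`).
#' @return data.frame `(stage, issue, detail)`.
#' @export
validate_inputs <- function(gps_csv = NULL, stack = NULL, fixes = NULL) {
  issues <- data.frame(stage = character(0), issue = character(0),
                       detail = character(0))
  add <- function(stage, issue, detail = "") {
    rbind(issues, data.frame(stage = stage, issue = issue,
                             detail = detail))
  }
  if (!is.null(gps_csv)) {
    if (!file.exists(gps_csv)) {
      issues <- add("gps", "file missing", gps_csv)
    } else {
      fixes <- tryCatch(read_gps_csv(gps_csv), error = function(e) {
        issues <<- add("gps", "schema error", conditionMessage(e))
        NULL
      })
      if (!is.null(fixes)) {
        bad <- attr(fixes, "issues")
        if (nrow(bad) > 0) {
          issues <- add("gps", "row-level problems",
                        paste(nrow(bad), "rows; first at line",
                              bad$line[1]))
        }
      }
    }
  }
  if (!is.null(stack)) {
    dims <- c(dim(stack$landcover), dim(stack$dist_development),
              dim(stack$dist_roads), dim(stack$ndvi)[1:2])
    if (length(unique(dims[c(1, 3, 5, 7)])) != 1 ||
        length(unique(dims[c(2, 4, 6, 8)])) != 1) {
      issues <- add("raster", "layer geometry mismatch",
                    paste(dims, collapse = "x"))
    }
    if (any(stack$ndvi < -1 | stack$ndvi > 1)) {
      issues <- add("raster", "NDVI outside [-1, 1]")
    }
  }
  if (!is.null(fixes) && !is.null(stack)) {
    rc <- xy_to_cell(stack, fixes$x, fixes$y)
    n_out <- sum(is.na(rc[, 1]))
    if (n_out > 0) {
      issues <- add("agreement", "fixes outside raster extent",
                    paste(n_out, "fixes"))
    }
    doy <- ((floor(study_day(fixes$timestamp)) - 1) %% 365) + 1
    covered <- max(stack$ndvi_period_start) + 7
    if (any(doy > covered)) {
      issues <- add("agreement", "fix dates beyond NDVI period coverage",
                    paste("days", paste(range(doy[doy > covered]),
                                        collapse = "-")))
    }
  }
  issues
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> classify -> ranges -> rsf ->
#' consistency with per-stage seeding, writing each stage's artifact as
#' plain CSV plus a JSON run manifest that records seeds, row counts, and
#' exclusion tallies. Re-running with an identical configuration
#' reproduces identical CSVs; stages toggled off are read back from their
#' cached CSVs, and a missing upstream artifact fails naming the stage.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param seed optional override of `config$seed`.
#' @param out_dir optional override of `config$out_dir`.
#' @return invisibly, a list with the manifest and in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("hierRSF")), seed = cfg$seed, stages = list())
  res <- list()
  path <- function(f) file.path(cfg$out_dir, f)

  # --- simulate / load -------------------------------------------------
  if (isTRUE(cfg$stages$simulate) && is.null(cfg$input$gps_csv)) {
    scen <- do.call(make_scenario, cfg$scenario)
    pop <- simulate_population(scen, seed = split_seed(cfg$seed, "simulate"))
    fixes <- pop$fixes
    res$population <- pop
    write_gps_csv(fixes, path("gps.csv"))
    utils::write.csv(pop$truth, path("truth.csv"), row.names = FALSE)
    utils::write.csv(pop$beta, path("beta_true.csv"), row.names = FALSE)
    manifest$stages$simulate <- list(
      seed = split_seed(cfg$seed, "simulate"),
      n_animals = nrow(pop$truth), n_fixes = nrow(fixes))
  } else if (!is.null(cfg$input$gps_csv)) {
    if (!file.exists(cfg$input$gps_csv)) {
      stop("stage 'simulate/load': input GPS CSV not found: ",
           cfg$input$gps_csv)
    }
    fixes <- read_gps_csv(cfg$input$gps_csv)
    res$population <- NULL
    manifest$stages$load <- list(n_fixes = nrow(fixes),
                                 n_issues = nrow(attr(fixes, "issues")))
  } else {
    if (!file.exists(path("gps.csv"))) {
      stop("stage 'classify': missing upstream artifact gps.csv ",
           "(simulate stage is off and no input was given)")
    }
    fixes <- read_gps_csv(path("gps.csv"))
  }
  res$fixes <- fixes

  # --- classify --------------------------------------------------------
  if (isTRUE(cfg$stages$classify)) {
    calls <- classify_population(fixes,
                                 min_months = cfg$classify$min_months,
                                 ambiguity_delta = cfg$classify$ambiguity_delta)
    season_table <- herd_median_dates(calls)
    utils::write.csv(calls, path("strategy_calls.csv"), row.names = FALSE)
    utils::write.csv(season_table, path("season_table.csv"),
                     row.names = FALSE)
    manifest$stages$classify <- list(
      n_animal_years = nrow(calls),
      tally = as.list(table(calls$strategy)))
  } else {
    if (!file.exists(path("strategy_calls.csv"))) {
      stop("stage 'ranges': missing upstream artifact strategy_calls.csv")
    }
    calls <- utils::read.csv(path("strategy_calls.csv"))
    class(calls) <- c("strategy_calls", "data.frame")
    season_table <- utils::read.csv(path("season_table.csv"))
  }
  res$calls <- calls
  res$season_table <- season_table

  # --- ranges ----------------------------------------------------------
  if (isTRUE(cfg$stages$ranges)) {
    strata <- build_strata(fixes, calls, season_table,
                           min_days = cfg$ranges$min_days,
                           min_fixes = cfg$ranges$min_fixes,
                           level = cfg$ranges$level)
    summ <- strata$summary
    utils::write.csv(summ, path("ranges_summary.csv"), row.names = FALSE)
    manifest$stages$ranges <- list(
      n_strata = nrow(summ),
      n_unclear_animals = length(strata$unclear),
      unclear = strata$unclear)
    res$strata <- strata
  } else if (isTRUE(cfg$stages$rsf)) {
    stop("stage 'rsf': requires the ranges stage (toggled off and ",
         "ranges are not cached in-memory)")
  }

  # --- rsf -------------------------------------------------------------
  if (isTRUE(cfg$stages$rsf)) {
    stack <- res$population$stack
    if (is.null(stack)) {
      stop("stage 'rsf': no covariate stack available ",
           "(real-raster input not configured)")
    }
    coefs <- fit_all_rsf(res$strata, stack,
                         n_available = cfg$rsf$n_available,
                         vif_threshold = cfg$rsf$vif_threshold,
                         estimator = cfg$rsf$estimator,
                         seed = split_seed(cfg$seed, "rsf"))
    utils::write.csv(coefs, path("rsf_coefficients.csv"),
                     row.names = FALSE)
    manifest$stages$rsf <- list(
      seed = split_seed(cfg$seed, "rsf"),
      n_models = length(unique(paste(coefs$herd, coefs$season,
                                     coefs$strategy))),
      estimator = cfg$rsf$estimator)
    res$coefficients <- coefs
  } else if (isTRUE(cfg$stages$consistency)) {
    if (!file.exists(path("rsf_coefficients.csv"))) {
      stop("stage 'consistency': missing upstream artifact ",
           "rsf_coefficients.csv (rsf stage is off)")
    }
    res$coefficients <- utils::read.csv(path("rsf_coefficients.csv"))
  }

  # --- consistency -----------------------------------------------------
  if (isTRUE(cfg$stages$consistency)) {
    ca <- consistency_analysis(res$coefficients,
                               B = cfg$consistency$B,
                               alpha = cfg$consistency$alpha,
                               seed = split_seed(cfg$seed, "consistency"))
    utils::write.csv(ca$scores, path("consistency_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(ca$pairwise, path("consistency_pairwise.csv"),
                     row.names = FALSE)
    utils::write.csv(ca$draws_long, path("consistency_draws.csv"),
                     row.names = FALSE)
    manifest$stages$consistency <- list(
      seed = split_seed(cfg$seed, "consistency"),
      B = cfg$consistency$B, alpha = cfg$consistency$alpha)
    res$consistency <- ca
  }

  # animal-year accounting: analyzed vs excluded-with-reason
  if (!is.null(res$calls)) {
    excl <- res$calls$strategy %in% c("excluded", "ambiguous", "disperser")
    unclear <- if (!is.null(res$strata)) res$strata$unclear else character(0)
    manifest$accounting <- list(
      n_total = nrow(res$calls),
      n_analyzed = sum(!excl & !res$calls$animal_id %in% unclear),
      n_excluded = sum(excl) + sum(!excl &
                                     res$calls$animal_id %in% unclear))
  }
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(list(manifest = manifest, out_dir = cfg$out_dir), res))
}

#' Build animal-season-year strata with delineated ranges
#'
#' Applies [assign_seasons()] per analyzable animal (migrant or resident
#' calls), delineates each usable seasonal range, and collects the strata
#' that feed the RSF design. Animals with fewer than two usable ranges are
#' tallied as unclear and dropped.
#'
#' @param fixes fix table.
#' @param calls `strategy_calls`.
#' @param season_table herd medians from [herd_median_dates()].
#' @param min_days,min_fixes usability thresholds.
#' @param level isopleth level.
#' @return list with `strata` (list of per-stratum records: ids, fixes,
#'   `seasonal_range`), `summary` (data.frame), `unclear` (animal ids).
#' @export
build_strata <- function(fixes, calls, season_table, min_days = 30,
                         min_fixes = 50, level = 0.95) {
  strata <- list()
  unclear <- character(0)
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    if (!call$strategy %in% c("migrant", "resident")) next
    traj <- fixes[fixes$animal_id == call$animal_id, ]
    lab <- assign_seasons(traj, call, season_table,
                          min_days = min_days, min_fixes = min_fixes)
    if (attr(lab, "unclear")) {
      unclear <- c(unclear, call$animal_id)
      next
    }
    for (rid in attr(lab, "usable_ranges")) {
      sub <- lab[!is.na(lab$range_id) & lab$range_id == rid, ]
      rng <- delineate_range(sub, id = call$animal_id,
                             season = sub$season[1], year = sub$year[1],
                             level = level)
      strata[[paste(call$animal_id, rid, sep = ".")]] <- list(
        stratum = paste(call$animal_id, rid, sep = "."),
        animal_id = call$animal_id, herd = call$herd,
        strategy = call$strategy, season = sub$season[1],
        year = sub$year[1], fixes = sub[, c("x", "y", "day")],
        range = rng)
    }
  }
  summary <- do.call(rbind, lapply(strata, function(s) data.frame(
    stratum = s$stratum, animal_id = s$animal_id, herd = s$herd,
    strategy = s$strategy, season = s$season, year = s$year,
    n_fixes = nrow(s$fixes), h_m = s$range$h,
    area_km2 = s$range$area_km2)))
  rownames(summary) <- NULL
  list(strata = strata, summary = summary, unclear = unclear)
}

#' Fit all herd-season-strategy RSF models
#'
#' Builds the used-available design per stratum (sampling availability
#' from each 95% isopleth), pools strata into herd-season-strategy
#' models, applies the VIF screen, and fits each model. The covariate set
#' is harmonized within each herd-season so the migrant and resident
#' models of a pair stay comparable.
#'
#' @param strata result of [build_strata()].
#' @param stack the `covariate_stack`.
#' @param n_available available points per stratum.
#' @param vif_threshold VIF exclusion threshold.
#' @param estimator passed to [fit_rsf()].
#' @param seed integer seed.
#' @return coefficient table: `herd, season, strategy, covariate, beta,
#'   se, beta_natural, se_natural, n_strata, estimator`.
#' @export
fit_all_rsf <- function(strata, stack, n_available = 10000,
                        vif_threshold = 10, estimator = "two_stage",
                        seed = 1L) {
  recs <- strata$strata
  hs_key <- vapply(recs, function(s) paste(s$herd, s$season, sep = "|"),
                   character(1))
  out <- list()
  for (hs in unique(hs_key)) {
    group <- recs[hs_key == hs]
    strategies <- unique(vapply(group, function(s) s$strategy,
                                character(1)))
    tabs <- list()
    covsets <- list()
    for (m in strategies) {
      sub <- group[vapply(group, function(s) s$strategy == m, logical(1))]
      parts <- lapply(sub, function(s) {
        av <- sample_available(s$range, n = n_available,
                               used_days = s$fixes$day,
                               seed = split_seed(seed, s$stratum))
        used <- s$fixes
        used$stratum <- s$stratum
        av$stratum <- s$stratum
        extract_design(used, av, stack)
      })
      tab <- suppressWarnings(preprocess_design(do.call(rbind, parts)))
      if (length(unique(tab$stratum)) < 2) next
      tabs[[m]] <- tab
      covsets[[m]] <- vif_filter(tab, threshold = vif_threshold)$covariates
    }
    if (length(tabs) == 0) next
    # keep the covariate set identical across the strategy pair within a
    # herd-season so the models stay comparable in consistency scoring
    common <- Reduce(intersect, covsets)
    fits <- lapply(tabs, function(tab) {
      fit_rsf(tab, covariates = common, estimator = estimator)
    })
    drop_k <- unique(unlist(lapply(fits, function(f) {
      f$coefficients$covariate[is.na(f$coefficients$beta)]
    })))
    parts <- strsplit(hs, "|", fixed = TRUE)[[1]]
    for (m in names(fits)) {
      cf <- fits[[m]]$coefficients
      cf <- cf[!cf$covariate %in% drop_k, ]
      cf$herd <- parts[1]; cf$season <- parts[2]; cf$strategy <- m
      cf$n_strata <- fits[[m]]$n_strata
      cf$estimator <- fits[[m]]$estimator
      out[[paste(hs, m)]] <- cf
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("herd", "season", "strategy", "covariate", "beta", "se",
          "beta_natural", "se_natural", "n_strata", "estimator")]
}

#' End-to-end consistency analysis of a coefficient table
#'
#' Computes every grouping score with its Monte Carlo distribution,
#' Dunnett's T3 letters across the main groupings, covariate-subset
#' scores per covariate group, and the migrant-prevalence correlation
#' when strategy proportions are supplied.
#'
#' @param coefs coefficient table (columns `herd, season, strategy,
#'   covariate, beta, se`).
#' @param B Monte Carlo draws per grouping.
#' @param alpha significance level for T3 letters.
#' @param seed integer seed.
#' @param migrant_props optional named vector of per-herd migrant
#'   proportions for the prevalence correlation.
#' @return list: `scores` (grouping, subset, mean, lo95, hi95, letter),
#'   `pairwise` (T3 p-values), `draws_long` (violin-ready long table),
#'   `t3`, and `prevalence` (if proportions given).
#' @export
consistency_analysis <- function(coefs, B = 10000, alpha = 0.05,
                                 seed = 1L, migrant_props = NULL) {
  cs <- as_coef_set(coefs[, c("herd", "season", "strategy", "covariate",
                              "beta", "se")])
  cs <- cs[cs$herd %in% complete_herds(cs), ]
  main <- c("among_herd", "between_season", "between_strategy",
            paste0("season_strategy:", unique(cs$season)))
  herd_groupings <- paste0("herd:", complete_herds(cs))
  dists <- list()
  rows <- list()
  draws_long <- list()
  gi <- 0
  for (g in c(main, herd_groupings)) {
    gi <- gi + 1
    d <- mc_distribution(cs, g, B = B, seed = split_seed(seed, gi))
    dists[[g]] <- d
    rows[[g]] <- data.frame(grouping = g, subset = "all", mean = d$mean,
                            lo95 = d$ci[1], hi95 = d$ci[2])
    draws_long[[g]] <- data.frame(grouping = g, subset = "all",
                                  draw = seq_len(B), value = d$draws)
  }
  t3 <- dunnett_t3(dists[main], alpha = alpha)
  subset_rows <- list()
  for (grp in unique(unname(COVARIATE_GROUPS[unique(cs$covariate)]))) {
    ks <- names(COVARIATE_GROUPS)[COVARIATE_GROUPS == grp]
    ks <- intersect(ks, unique(cs$covariate))
    if (length(ks) == 0) next
    for (g in main) {
      gi <- gi + 1
      d <- mc_distribution(cs, g, subset = ks, B = B,
                           seed = split_seed(seed, gi))
      subset_rows[[paste(g, grp)]] <- data.frame(
        grouping = g, subset = grp, mean = d$mean, lo95 = d$ci[1],
        hi95 = d$ci[2])
      draws_long[[paste(g, grp)]] <- data.frame(
        grouping = g, subset = grp, draw = seq_len(B), value = d$draws)
    }
  }
  scores <- rbind(do.call(rbind, rows), do.call(rbind, subset_rows))
  scores$letter <- t3$letters[scores$grouping]
  scores$letter[scores$subset != "all"] <- NA
  rownames(scores) <- NULL
  out <- list(scores = scores, pairwise = t3$pairs,
              draws_long = do.call(rbind, draws_long), t3 = t3,
              dists = dists)
  if (!is.null(migrant_props)) {
    hs <- vapply(herd_groupings, function(g) dists[[g]]$mean, numeric(1))
    names(hs) <- sub("^herd:", "", herd_groupings)
    common <- intersect(names(hs), names(migrant_props))
    out$prevalence <- prevalence_correlation(hs[common],
                                             migrant_props[common])
  }
  out
}
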