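#' Sample available locations from a seasonal range
#'
#' Availability for third-order selection is the animal's own seasonal
#' range: points are drawn uniformly over the 95% isopleth cells (uniform
#' within each cell), and each available point receives a date drawn with
#' replacement from the used-fix dates of the same stratum, so
#' time-indexed covariates (NDVI) are sampled on the season's footprint.
#'
#' @param range a `seasonal_range`.
#' @param n number of available points (10,000 in the standard design).
#' @param used_days study days of the stratum's used fixes.
#' @param seed integer seed.
#' @return data.frame `(x, y, day)`.
#' @export
sample_available <- function(range, n = 10000, used_days, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  cells <- which(range$mask)
  if (length(cells) == 0) stop("empty isopleth: nothing is available")
  set.seed(seed)
  ud <- range$ud
  pick <- cells[sample.int(length(cells), n, replace = TRUE)]
  r <- ((pick - 1) %% ud$n_rows) + 1
  cl <- ((pick - 1) %/% ud$n_rows) + 1
  cs <- ud$cell_size
  data.frame(
    x = ud$origin[1] + (cl - 1 + stats::runif(n)) * cs,
    y = ud$origin[2] + (r - 1 + stats::runif(n)) * cs,
    day = sample(used_days, n, replace = TRUE)
  )
}

#' Build the used-available design table
#'
#' Extracts the model covariates at used fixes and available points
#' against a covariate stack: landcover indicators with forest as the
#' reference category, distances in meters, and NDVI matched to the 8-day
#' period containing each point's date. Points falling outside the stack
#' are dropped and counted.
#'
#' @param used data.frame of used fixes with `x, y, day` (and optionally
#'   `stratum`).
#' @param available data.frame from [sample_available()].
#' @param stack a `covariate_stack`.
#' @param stratum stratum identifier (animal-season-year) stamped on all
#'   rows when the inputs carry none.
#' @return data.frame with `stratum, used, day`, raw covariates
#'   (`crops, herbaceous, other, dist_development, dist_roads, ndvi`);
#'   attribute `n_dropped` counts out-of-bounds points.
#' @export
extract_design <- function(used, available, stack, stratum = "s1") {
  build <- function(pts, flag) {
    cov <- extract_covariates(stack, pts$x, pts$y, pts$day)
    out <- cbind(
      data.frame(stratum = if ("stratum" %in% names(pts)) pts$stratum
                 else stratum,
                 used = flag, day = pts$day),
      cov[, c("crops", "herbaceous", "other", "dist_development",
              "dist_roads", "ndvi")]
    )
    out
  }
  tab <- rbind(build(used, 1L), build(available, 0L))
  ok <- stats::complete.cases(tab)
  out <- tab[ok, ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Transform and scale a design table
#'
#' Distance covariates become `ln(d + 1)` (d in meters); the continuous
#' covariates (log-distances and NDVI) are then centered and scaled by the
#' mean and SD of the table's own pooled rows. The scaling constants are
#' recorded so coefficients can be back-transformed to the natural scale.
#' Covariates with zero variance are dropped with a warning.
#'
#' @param tab design table from [extract_design()].
#' @return the model-ready table with covariates
#'   `crops, herbaceous, other, ln_dist_development, ln_dist_roads, ndvi`;
#'   attributes `scaling` (data.frame covariate/mean/sd) and `covariates`
#'   (retained set).
#' @export
preprocess_design <- function(tab) {
  tab$ln_dist_development <- log1p(tab$dist_development)
  tab$ln_dist_roads <- log1p(tab$dist_roads)
  tab$dist_development <- NULL
  tab$dist_roads <- NULL
  continuous <- c("ln_dist_development", "ln_dist_roads", "ndvi")
  scaling <- data.frame(covariate = continuous, mean = NA_real_,
                        sd = NA_real_)
  keep <- RSF_COVARIATES
  for (i in seq_along(continuous)) {
    v <- tab[[continuous[i]]]
    m <- mean(v); s <- stats::sd(v)
    scaling$mean[i] <- m
    scaling$sd[i] <- s
    if (!is.finite(s) || s == 0) {
      warning("covariate ", continuous[i], " has zero variance; dropped")
      keep <- setdiff(keep, continuous[i])
      tab[[continuous[i]]] <- NULL
    } else {
      tab[[continuous[i]]] <- (v - m) / s
    }
  }
  for (k in c("crops", "herbaceous", "other")) {
    if (stats::sd(tab[[k]]) == 0) {
      warning("covariate ", k, " has zero variance; dropped")
      keep <- setdiff(keep, k)
      tab[[k]] <- NULL
    }
  }
  attr(tab, "scaling") <- scaling
  attr(tab, "covariates") <- keep
  tab
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from the linear regression of covariate `k`
#' on the remaining covariates, computed on the available rows only (the
#' availability sample characterizes the landscape's collinearity
#' structure).
#'
#' @param tab model-ready table from [preprocess_design()].
#' @param covariates covariate columns to assess.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(tab, covariates = attr(tab, "covariates")) {
  av <- tab[tab$used == 0, covariates, drop = FALSE]
  out <- vapply(covariates, function(k) {
    others <- setdiff(covariates, k)
    if (length(others) == 0) return(1)
    fit <- stats::lm(stats::reformulate(others, response = k), data = av)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- covariates
  out
}

#' Iterative VIF filter
#'
#' Repeatedly drops the highest-VIF covariate while any VIF is at or above
#' the threshold (10 in the standard screen).
#'
#' @inheritParams vif
#' @param threshold exclusion threshold.
#' @return list with `covariates` (retained), `dropped` (named vector of
#'   the VIF each covariate had when dropped), `vif` (final VIFs).
#' @export
vif_filter <- function(tab, covariates = attr(tab, "covariates"),
                       threshold = 10) {
  if (length(covariates) < 2) stop("need at least two covariates")
  dropped <- numeric(0)
  repeat {
    v <- vif(tab, covariates)
    if (all(v < threshold)) break
    worst <- names(v)[which.max(v)]
    dropped[worst] <- v[[worst]]
    covariates <- setdiff(covariates, worst)
    if (length(covariates) < 2) {
      if (length(covariates) == 0) stop("all covariates collinear")
      break
    }
  }
  list(covariates = covariates, dropped = dropped,
       vif = vif(tab, covariates))
}

#' Fit a resource selection function
#'
#' Estimates population-level selection coefficients from a used-available
#' design with animal-season-year strata, accounting for among-stratum
#' coefficient heterogeneity. Two estimators are provided:
#' \describe{
#'   \item{`two_stage` (default)}{an unconditional logistic fit per
#'     stratum, pooled per covariate by inverse-variance weighting with a
#'     method-of-moments (DerSimonian-Laird) between-stratum variance via
#'     [metafor::rma.uni()] — the meta-analytic mirror of a random-slopes
#'     model.}
#'   \item{`mixed`}{a mixed-effects logistic regression with a random
#'     intercept and independent random slopes per stratum (glmmTMB),
#'     the formulation usual for exponential RSFs.}
#' }
#' Strata showing separation (unbounded coefficients) are excluded from
#' two-stage pooling with a warning.
#'
#' @param tab model-ready table from [preprocess_design()] with at least
#'   two strata.
#' @param covariates covariates to fit (post VIF filter).
#' @param estimator `"two_stage"` or `"mixed"`.
#' @return object of class `rsf_fit` with a `coefficients` data.frame
#'   (`covariate, beta, se, beta_natural, se_natural`), `n_strata`,
#'   `dropped_strata`, `estimator`, and the `scaling` record.
#' @export
fit_rsf <- function(tab, covariates = attr(tab, "covariates"),
                    estimator = c("two_stage", "mixed")) {
  estimator <- match.arg(estimator)
  strata <- unique(tab$stratum)
  if (length(strata) < 2) stop("need at least two strata to pool")
  for (s in strata) {
    u <- tab$used[tab$stratum == s]
    if (all(u == 0) || all(u == 1)) {
      stop("stratum ", s, " lacks used or available rows")
    }
  }
  form <- stats::reformulate(covariates, response = "used")

  if (estimator == "mixed") {
    if (!requireNamespace("glmmTMB", quietly = TRUE)) {
      stop("estimator 'mixed' requires the glmmTMB package")
    }
    re <- paste0("(1 + ", paste(covariates, collapse = " + "),
                 " || stratum)")
    f <- stats::as.formula(paste("used ~",
                                 paste(covariates, collapse = " + "),
                                 "+", re))
    fit <- glmmTMB::glmmTMB(f, data = tab, family = stats::binomial())
    sm <- summary(fit)$coefficients$cond
    beta <- sm[covariates, "Estimate"]
    se <- sm[covariates, "Std. Error"]
    dropped_strata <- character(0)
  } else {
    mat <- matrix(NA_real_, length(strata), length(covariates),
                  dimnames = list(strata, covariates))
    sem <- mat
    bad <- character(0)
    for (s in strata) {
      sub <- tab[tab$stratum == s, ]
      g <- suppressWarnings(stats::glm(form, data = sub,
                                       family = stats::binomial()))
      cf <- summary(g)$coefficients
      have <- intersect(covariates, rownames(cf))
      if (!g$converged || length(have) == 0) {
        bad <- c(bad, s)
        next
      }
      mat[s, have] <- cf[have, "Estimate"]
      sem[s, have] <- cf[have, "Std. Error"]
    }
    # a stratum informs a covariate only where the estimate is bounded
    # (separation or an absent landcover class in the range shows up as a
    # diverging coefficient or a rank-deficient fit)
    valid <- is.finite(mat) & is.finite(sem) & abs(mat) <= 15 & sem <= 50
    n_bad_cells <- sum(!valid)
    if (length(bad) || n_bad_cells) {
      warning("separation or degenerate covariates: ", length(bad),
              " strata unfit, ", n_bad_cells,
              " stratum-covariate estimates excluded from pooling")
    }
    if (max(colSums(valid)) < 2) {
      stop("fewer than two strata survived per-stratum fits")
    }
    beta <- se <- stats::setNames(rep(NA_real_, length(covariates)),
                                  covariates)
    for (k in covariates) {
      ok <- valid[, k]
      if (sum(ok) < 2) {
        warning("covariate ", k, " informed by fewer than two strata; NA")
        next
      }
      rm <- metafor::rma.uni(yi = mat[ok, k], sei = sem[ok, k],
                             method = "DL")
      beta[k] <- as.numeric(rm$beta)
      se[k] <- rm$se
    }
    dropped_strata <- bad
  }

  scaling <- attr(tab, "scaling")
  sdv <- stats::setNames(rep(1, length(covariates)), covariates)
  if (!is.null(scaling)) {
    m <- match(covariates, scaling$covariate)
    sdv[!is.na(m)] <- scaling$sd[m[!is.na(m)]]
  }
  coefs <- data.frame(
    covariate = covariates,
    beta = unname(beta), se = unname(se),
    beta_natural = unname(beta / sdv), se_natural = unname(se / sdv)
  )
  structure(list(
    coefficients = coefs,
    n_strata = length(strata) - length(dropped_strata),
    dropped_strata = dropped_strata,
    estimator = estimator, scaling = scaling
  ), class = "rsf_fit")
}

#' @export
coef.rsf_fit <- function(object, scale = c("standardized", "natural"),
                         ...) {
  scale <- match.arg(scale)
  cf <- object$coefficients
  stats::setNames(if (scale == "natural") cf$beta_natural else cf$beta,
                  cf$covariate)
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("<rsf_fit> ", x$estimator, " estimator, ", x$n_strata, " strata\n",
      sep = "")
  cf <- x$coefficients
  cf$z <- cf$beta / cf$se
  print(cf, row.names = FALSE, digits = 3)
  invisible(x)
}
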