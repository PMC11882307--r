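one_cell_range <- function() {
  mask <- matrix(FALSE, 5, 5)
  mask[3, 4] <- TRUE
  structure(list(
    animal_id = "a", season = "winter", year = 1,
    ud = structure(list(origin = c(0, 0), cell_size = 100, n_rows = 5,
                        n_cols = 5, density = mask / 100^2, h = 100, n = 1),
                   class = "ud_grid"),
    mask = mask, area_km2 = 0.01, level = 0.95, h = 100, n = 1
  ), class = "seasonal_range")
}

test_that("available points stay inside the isopleth with resampled dates", {
  rng <- one_cell_range()
  av <- sample_available(rng, n = 500, used_days = c(10, 11, 12), seed = 1)
  expect_true(all(av$x > 300 & av$x < 400))
  expect_true(all(av$y > 200 & av$y < 300))
  expect_true(all(av$day %in% c(10, 11, 12)))
  expect_identical(av, sample_available(rng, 500, c(10, 11, 12), seed = 1))
  expect_error(sample_available(rng, n = 0, used_days = 1), "positive")
})

test_that("resampled dates are uniform over the season window", {
  set.seed(2)
  pts <- data.frame(x = rnorm(300, 0, 600), y = rnorm(300, 0, 600))
  rng <- delineate_range(pts)
  window <- 150:209
  av <- sample_available(rng, n = 10000, used_days = window, seed = 3)
  tab <- table(factor(av$day, levels = window))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("design extraction uses forest as reference and matches NDVI", {
  stack <- tiny_stack()
  rc <- which(stack$landcover == 1, arr.ind = TRUE)[1, ]
  x <- stack$origin[1] + (rc[2] - 0.5) * stack$cell_size
  y <- stack$origin[2] + (rc[1] - 0.5) * stack$cell_size
  used <- data.frame(x = x, y = y, day = 20)
  av <- data.frame(x = x, y = y, day = 30)
  tab <- extract_design(used, av, stack, stratum = "s")
  expect_equal(tab$crops, c(0, 0))
  expect_equal(tab$herbaceous, c(0, 0))
  expect_equal(tab$other, c(0, 0))
  expect_equal(tab$ndvi,
               stack$ndvi[cbind(rc[1], rc[2],
                                ndvi_period(stack, c(20, 30)))])
  # out-of-bounds points are dropped and counted
  used2 <- rbind(used, data.frame(x = -1e7, y = 0, day = 20))
  tab2 <- extract_design(used2, av, stack)
  expect_equal(attr(tab2, "n_dropped"), 1)
  expect_equal(nrow(tab2), 2)
})

test_that("preprocessing applies ln(d+1) then centers and scales", {
  tab <- data.frame(
    stratum = "s", used = rep(0:1, each = 10), day = 1,
    crops = rep(0:1, 10), herbaceous = rep(c(0, 0, 1, 1), 5),
    other = rep(c(1, 0), 10),
    dist_development = c(0, exp(1) - 1, runif(18, 0, 5000)),
    dist_roads = runif(20, 0, 3000), ndvi = runif(20, 0, 1)
  )
  pp <- preprocess_design(tab)
  sc <- attr(pp, "scaling")
  ln_dev <- sc[sc$covariate == "ln_dist_development", ]
  raw <- pp$ln_dist_development * ln_dev$sd + ln_dev$mean
  expect_equal(raw[1], 0)           # ln(0 + 1)
  expect_equal(raw[2], 1)           # ln(e - 1 + 1)
  expect_equal(mean(pp$ln_dist_development), 0, tolerance = 1e-12)
  expect_equal(sd(pp$ln_dist_development), 1, tolerance = 1e-12)
  expect_equal(mean(pp$ndvi), 0, tolerance = 1e-12)
  # back-transform round trip
  expect_equal(raw, log1p(tab$dist_development), tolerance = 1e-12)
  # zero-variance covariates are dropped with a warning
  tab$ndvi <- 0.5
  expect_warning(pp2 <- preprocess_design(tab), "zero variance")
  expect_false("ndvi" %in% attr(pp2, "covariates"))
})

test_that("VIF matches its closed form and filters iteratively", {
  set.seed(5)
  n <- 4000
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1 <- (z1 - mean(z1)) / sd(z1)
  z2 <- residuals(lm(z2 ~ z1)); z2 <- (z2 - mean(z2)) / sd(z2)
  x2 <- 0.9 * z1 + sqrt(1 - 0.81) * z2   # empirical correlation exactly 0.9
  tab <- data.frame(stratum = "s", used = 0, day = 1,
                    a = z1, b = x2, c = rnorm(n))
  v2 <- vif(tab, c("a", "b"))
  expect_equal(unname(v2["a"]), 1 / (1 - 0.81), tolerance = 1e-9)
  expect_equal(unname(v2["b"]), 5.263, tolerance = 1e-3)
  v <- vif(tab, c("a", "b", "c"))
  expect_equal(unname(v["a"]), 1 / (1 - 0.81), tolerance = 1e-3)
  vf <- vif_filter(tab, c("a", "b", "c"), threshold = 10)
  expect_setequal(vf$covariates, c("a", "b", "c"))  # 5.26 < 10: retained

  # orthogonal covariates: all VIFs ~ 1
  tab2 <- data.frame(stratum = "s", used = 0, day = 1,
                     a = rep(c(1, -1), 8), b = rep(c(1, 1, -1, -1), 4),
                     c = rep(c(1, 1, 1, 1, -1, -1, -1, -1), 2))
  expect_equal(unname(vif(tab2, c("a", "b", "c"))), rep(1, 3),
               tolerance = 1e-9)

  # a duplicated covariate is perfectly collinear: one of the pair drops
  tab3 <- tab
  tab3$b <- tab3$a
  vf3 <- suppressWarnings(vif_filter(tab3, c("a", "b", "c"),
                                     threshold = 10))
  expect_equal(length(vf3$covariates), 2)
  expect_true("c" %in% vf3$covariates)
  expect_length(vf3$dropped, 1)

  expect_error(vif_filter(tab, "a"), "two covariates")
})

test_that("two-stage RSF matches a pooled-logistic oracle on planted data", {
  stack <- tiny_stack()
  beta <- c(crops = 0, herbaceous = 0, other = 0,
            ln_dist_development = 0, ln_dist_roads = 0, ndvi = 0.5)
  tab <- design_sim(stack, beta, n_strata = 8, n_used = 400,
                    n_avail = 2000, seed = 31)
  fit <- suppressWarnings(fit_rsf(tab))
  expect_equal(fit$estimator, "two_stage")
  expect_gt(fit$n_strata, 5)
  # oracle: one logistic over the pooled rows, ignoring strata
  orc <- stats::glm(stats::reformulate(RSF_COVARIATES, "used"),
                    data = tab, family = stats::binomial())
  expect_equal(unname(coef(fit)["ndvi"]),
               unname(stats::coef(orc)["ndvi"]), tolerance = 0.15)
  # natural-scale back-transform recovers the planted effect direction
  expect_gt(unname(coef(fit, "natural")["ndvi"]), 0.2)
})

test_that("swapping used/available labels flips coefficient signs", {
  stack <- tiny_stack()
  beta <- c(crops = 0.8, herbaceous = -0.5, other = 0,
            ln_dist_development = 0.4, ln_dist_roads = 0, ndvi = 0.6)
  tab <- design_sim(stack, beta, n_strata = 4, n_used = 300,
                    n_avail = 1200, seed = 7)
  f1 <- suppressWarnings(fit_rsf(tab))
  tab2 <- tab
  tab2$used <- 1L - tab2$used
  f2 <- suppressWarnings(fit_rsf(tab2))
  expect_equal(unname(coef(f2)), -unname(coef(f1)), tolerance = 1e-6)
})

test_that("degenerate strata are excluded from pooling, not fatal", {
  stack <- tiny_stack()
  beta <- rep(0, 6)
  names(beta) <- RSF_COVARIATES
  tab <- design_sim(stack, beta, n_strata = 3, n_used = 150,
                    n_avail = 600, seed = 13)
  # make one stratum's crops column constant: separation-like degeneracy
  tab$crops[tab$stratum == "s1"] <- 0
  expect_warning(fit <- fit_rsf(tab), "separation|degenerate")
  expect_true(all(is.finite(fit$coefficients$se)))
  expect_error(fit_rsf(tab[tab$stratum == "s1", ]), "two strata")
})
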