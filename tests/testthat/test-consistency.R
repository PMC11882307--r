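# independent double-loop oracle for the consistency score
oracle_score <- function(df, vary, fixed, subset = NULL) {
  sub <- df
  for (nm in names(fixed)) sub <- sub[sub[[nm]] == fixed[[nm]], ]
  if (!is.null(subset)) sub <- sub[sub$covariate %in% subset, ]
  lv <- unique(sub[[vary]])
  tot <- 0
  cnt <- 0
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    for (k in unique(sub$covariate)) {
      bi <- sub$beta[sub[[vary]] == lv[i] & sub$covariate == k]
      bj <- sub$beta[sub[[vary]] == lv[j] & sub$covariate == k]
      tot <- tot + abs(bi - bj)
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

test_that("the consistency score enumerates unordered pairs", {
  g <- expand.grid(herd = c("A", "B", "C"), season = "winter",
                   strategy = "migrant", covariate = "k",
                   stringsAsFactors = FALSE)
  g$beta <- c(1, 2, 4)
  g$se <- 1
  cs <- as_coef_set(g)
  fx <- list(season = "winter", strategy = "migrant")
  expect_equal(consistency_score(cs, "herd", fx), 2)  # (1 + 3 + 2) / 3

  # identical vectors give zero; adding a constant changes nothing
  g0 <- g
  g0$beta <- 5
  expect_equal(consistency_score(as_coef_set(g0), "herd", fx), 0)
  g1 <- g
  g1$beta <- g$beta + 100
  expect_equal(consistency_score(as_coef_set(g1), "herd", fx), 2)

  # a hole in the grid is rejected by name
  g2 <- expand.grid(herd = c("A", "B", "C"), season = "winter",
                    strategy = "migrant", covariate = c("k1", "k2"),
                    stringsAsFactors = FALSE)
  g2$beta <- 1
  g2$se <- 1
  holed <- as_coef_set(g2[-2, ])  # drop (B, k1)
  expect_error(consistency_score(holed, "herd", fx), "hole")
  expect_error(consistency_score(cs[cs$herd == "A", ], "herd", fx),
               "two levels")
})

test_that("grouping scores isolate the varying dimension", {
  # herds differ by +2 in every beta; seasons and strategies identical
  g <- coef_grid(herds = c("A", "B"), covariates = c("k1", "k2"))
  g$beta <- ifelse(g$herd == "B", 2, 0)
  sc <- suppressMessages(grouping_scores(g))
  expect_equal(unname(sc[["among_herd"]]), 2)
  expect_equal(unname(sc[["between_season"]]), 0)
  expect_equal(unname(sc[["between_strategy"]]), 0)

  # permuting herd labels leaves among_herd unchanged
  g2 <- g
  g2$herd <- ifelse(g$herd == "A", "B", "A")
  sc2 <- suppressMessages(grouping_scores(g2))
  expect_equal(sc2[["among_herd"]], sc[["among_herd"]])

  # all equal -> every grouping is zero
  sc0 <- suppressMessages(grouping_scores(coef_grid(beta = 3)))
  expect_true(all(sc0 == 0))
})

test_that("scores agree with the double-loop oracle on random grids", {
  set.seed(42)
  for (r in 1:100) {
    g <- coef_grid(herds = c("A", "B", "C"),
                   covariates = paste0("k", 1:4),
                   beta = rnorm(48), se = runif(48, 0.05, 0.2))
    vary <- sample(c("herd", "season", "strategy"), 1)
    fixed <- list(season = sample(c("winter", "summer"), 1),
                  strategy = sample(c("migrant", "resident"), 1),
                  herd = "A")
    fixed <- fixed[setdiff(names(fixed), vary)]
    expect_equal(consistency_score(g, vary, fixed),
                 oracle_score(g, vary, fixed), tolerance = 1e-12)
  }
})

test_that("herds lacking a strategy are dropped from comparisons", {
  g <- coef_grid(herds = c("A", "B"))
  extra <- g[g$herd == "A" & g$strategy == "migrant", ]
  extra$herd <- "onlymig"
  g2 <- rbind(as.data.frame(g), extra)
  expect_message(sc <- grouping_scores(as_coef_set(g2)), "onlymig")
  expect_false("herd:onlymig" %in% names(sc))
})

test_that("Monte Carlo propagation is seeded and collapses as SE -> 0", {
  g <- coef_grid(herds = c("A", "B"), beta = rnorm(16), se = 1e-9)
  point <- suppressMessages(grouping_scores(g))[["among_herd"]]
  d <- mc_distribution(g, "among_herd", B = 500, seed = 3)
  expect_equal(d$mean, point, tolerance = 1e-6)
  expect_lt(diff(d$ci), 1e-6)

  g$se <- 0.3
  d1 <- mc_distribution(g, "among_herd", B = 500, seed = 3)
  d2 <- mc_distribution(g, "among_herd", B = 500, seed = 3)
  expect_identical(d1$draws, d2$draws)
  expect_warning(mc_distribution(g, "among_herd", B = 50), "unstable")
})

test_that("Dunnett T3 separates distinct groups and merges identical ones", {
  set.seed(8)
  same <- rnorm(400)
  t3 <- dunnett_t3(list(a = same, b = same))
  expect_equal(t3$pairs$p, 1)
  expect_equal(unname(t3$letters[1]), unname(t3$letters[2]))

  far <- dunnett_t3(list(lo = rnorm(1000, 0, 0.1),
                         hi = rnorm(1000, 10, 0.1)))
  expect_lt(far$pairs$p, 1e-6)
  expect_false(far$letters["lo"] == far$letters["hi"])

  # SMM p-values are never smaller than the unadjusted Welch p
  set.seed(9)
  gs <- lapply(1:4, function(i) rnorm(200, i * 0.05))
  names(gs) <- paste0("g", 1:4)
  t34 <- dunnett_t3(gs)
  welch_p <- apply(t34$pairs, 1, function(r) {
    stats::t.test(gs[[r[["a"]]]], gs[[r[["b"]]]])$p.value
  })
  expect_true(all(t34$pairs$p >= welch_p - 1e-10))
})

test_that("the SMM distribution matches simulation at small df", {
  # max |T| of r t-variates sharing one chi denominator, nu df
  set.seed(10)
  r <- 3; nu <- 12
  z <- matrix(rnorm(20000 * r), ncol = r)
  s <- sqrt(rchisq(20000, nu) / nu)
  m <- apply(abs(z / s), 1, max)
  for (q in c(1.5, 2.5, 3.5)) {
    expect_equal(hierRSF:::psmm(q, r, nu), mean(m <= q), tolerance = 0.02)
  }
})

test_that("prevalence correlation reproduces exact linear cases", {
  expect_equal(prevalence_correlation(c(4, 3, 2, 1),
                                      c(0.25, 0.5, 0.75, 1))$r, -1)
  p <- prevalence_correlation(c(1, 2, 3), c(0.1, 0.2, 0.3))
  expect_equal(p$r, 1)
  expect_error(prevalence_correlation(c(1, 1, 1), c(0.1, 0.2, 0.3)),
               "constant")
  expect_error(prevalence_correlation(c(1, 2), c(0.1, 0.2)), "three")
})

test_that("strategy proportions use Goodman simultaneous intervals", {
  calls <- data.frame(
    animal_id = sprintf("a%03d", 1:100), herd = "H",
    strategy = rep(c("migrant", "resident"), each = 50)
  )
  sp <- strategy_proportions(calls)
  expect_equal(sp$prop, c(0.5, 0.5, 0, 0))
  expect_equal(sum(sp$prop), 1)
  # Goodman closed form at alpha = 0.05, k = 4 categories
  A <- qchisq(1 - 0.05 / 4, 1)
  n <- 100; x <- 50
  lo <- (A + 2 * x - sqrt(A * (A + 4 * x * (n - x) / n))) / (2 * (n + A))
  expect_equal(sp$lower[1], lo, tolerance = 1e-12)

  # simulation oracle: simultaneous coverage of the true proportions
  set.seed(11)
  p_true <- c(0.5, 0.5, 0, 0)
  hit <- replicate(2000, {
    cnt <- as.vector(rmultinom(1, 100, p_true))
    sim <- data.frame(animal_id = "x", herd = "H",
                      strategy = rep(c("migrant", "resident", "ambiguous",
                                       "disperser"), cnt))
    ci <- strategy_proportions(sim)
    all(p_true >= ci$lower - 1e-12 & p_true <= ci$upper + 1e-12)
  })
  expect_gte(mean(hit), 0.93)

  # all-migrant herd: proportion 1 with upper bound 1
  allm <- data.frame(animal_id = 1:20, herd = "H", strategy = "migrant")
  spm <- strategy_proportions(allm)
  expect_equal(spm$prop[1], 1)
  expect_equal(spm$upper[1], 1)
})

test_that("every Monte Carlo consistency draw is non-negative", {
  g <- coef_grid(herds = c("A", "B", "C"), beta = rnorm(24), se = 0.5)
  for (grp in c("among_herd", "between_season", "between_strategy")) {
    d <- mc_distribution(g, grp, B = 300, seed = 4)
    expect_true(all(d$draws >= 0))
  }
})
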