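test_that("zero selection yields used covariates matching availability", {
  stack <- tiny_stack()
  scen <- tiny_scenario(beta_grid = {
    g <- make_beta_grid(c("A", "B"))
    g$beta <- 0
    g
  })
  truth <- data.frame(
    animal_id = "Z1", herd = "A", strategy = "resident",
    start_day = 10, span_days = 240, fix_interval_h = 1,
    c1x = 10000, c1y = 10000, c2x = NA, c2y = NA,
    theta1 = 150, phi1 = 3, theta2 = 280, phi2 = 3,
    dep1 = NA, arr1 = NA, dep2 = NA, arr2 = NA, sep_km = 0
  )
  traj <- simulate_trajectory(truth, stack, scen$beta_grid, scen, seed = 5)
  day <- study_day(traj$timestamp)
  used <- extract_covariates(stack, traj$x, traj$y, day)
  # reference: uniform draws over the same disc and days
  set.seed(99)
  n <- 20000
  r <- scen$range_radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  ref <- extract_covariates(stack, 10000 + r * cos(a), 10000 + r * sin(a),
                            sample(day, n, replace = TRUE))
  expect_equal(mean(used$ndvi), mean(ref$ndvi), tolerance = 0.02)
  expect_equal(mean(used$herbaceous), mean(ref$herbaceous),
               tolerance = 0.03)
  expect_equal(mean(used$dist_roads), mean(ref$dist_roads),
               tolerance = 0.05 * mean(ref$dist_roads) + 50)
})

test_that("positive selection enriches used points beyond availability", {
  stack <- tiny_stack()
  # strong selection for herbaceous only, tested across three seeds
  g <- make_beta_grid(c("A", "B"))
  g$beta <- ifelse(g$covariate == "herbaceous", 2, 0)
  scen <- tiny_scenario(beta_grid = g)
  truth <- data.frame(
    animal_id = "E1", herd = "A", strategy = "resident",
    start_day = 10, span_days = 240, fix_interval_h = 1,
    c1x = 11000, c1y = 9000, c2x = NA, c2y = NA,
    theta1 = 150, phi1 = 3, theta2 = 280, phi2 = 3,
    dep1 = NA, arr1 = NA, dep2 = NA, arr2 = NA, sep_km = 0
  )
  set.seed(1)
  avail <- local({
    n <- 20000
    r <- scen$range_radius * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    extract_covariates(stack, 11000 + r * cos(a), 9000 + r * sin(a), 30)
  })
  for (seed in c(2, 3, 4)) {
    traj <- simulate_trajectory(truth, stack, g, scen, seed = seed)
    expect_gt(nrow(traj), 5000)
    used <- extract_covariates(stack, traj$x, traj$y,
                               study_day(traj$timestamp))
    expect_gt(mean(used$herbaceous), mean(avail$herbaceous))
  }
})

test_that("migrant NSD plateaus near the squared center separation", {
  pop <- tiny_pop()
  truth <- pop$truth
  for (i in seq_len(nrow(truth))) {
    traj <- pop$fixes[pop$fixes$animal_id == truth$animal_id[i], ]
    nsd <- compute_nsd(traj)
    if (truth$strategy[i] == "migrant") {
      mid <- nsd$nsd[nsd$t > truth$arr1[i] - truth$start_day[i] &
                       nsd$t < truth$dep2[i] - truth$start_day[i]]
      expect_equal(mean(mid), truth$sep_km[i]^2,
                   tolerance = 0.2 * truth$sep_km[i]^2)
    } else {
      expect_lt(max(nsd$nsd), 0.25 * min(truth$sep_km[truth$sep_km > 0])^2)
    }
  }
})

test_that("population simulation is reproducible and respects the design", {
  scen <- tiny_scenario()
  a <- simulate_population(scen, seed = 21)
  b <- simulate_population(scen, seed = 21)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$truth, b$truth)

  # strategy mix per herd follows migrant_prop
  expect_equal(sum(a$truth$strategy == "migrant" & a$truth$herd == "A"), 2)
  # all-migrant herd contains no residents
  scen2 <- make_scenario(herds = data.frame(herd = "M", n = 4,
                                            migrant_prop = 1),
                         fix_interval_h = 4, sep_km = 10,
                         range_radius = 2000, landscape = tiny_stack())
  m <- simulate_population(scen2, seed = 1)
  expect_true(all(m$truth$strategy == "migrant"))
  # fixes per animal = span / interval + 1 (4105 at 2-h fixes over 342 d)
  expect_equal(unname(table(a$fixes$animal_id)[a$truth$animal_id[1]]),
               floor(342 * 24 / 4) + 1)
  expect_equal(floor(342 * 24 / 2) + 1, 4105)
  expect_error(make_scenario(herds = data.frame(herd = "X", n = 0,
                                                migrant_prop = 1)),
               "positive")
})

test_that("animals with centers outside the landscape are rejected", {
  scen <- tiny_scenario()
  truth <- simulate_population(scen, seed = 1)$truth[1, ]
  truth$c1x <- -5e5
  expect_error(simulate_trajectory(truth, tiny_stack(), scen$beta_grid,
                                   scen, seed = 1),
               "outside the landscape")
})

test_that("beta grids carry the planted differentiation structure", {
  g <- make_beta_grid(c("A", "B", "C"))
  expect_setequal(unique(g$covariate), RSF_COVARIATES)
  expect_equal(nrow(g), 3 * 2 * 2 * 6)
  tru <- g
  tru$se <- 1e-9
  sc <- suppressMessages(grouping_scores(as_coef_set(tru)))
  expect_gt(sc[["among_herd"]], sc[["between_season"]])
  expect_gt(sc[["between_season"]], sc[["between_strategy"]])

  ga <- make_beta_grid(c("A", "B"), anthropogenic_only = TRUE)
  tru <- ga
  tru$se <- 1e-9
  anth <- names(COVARIATE_GROUPS)[COVARIATE_GROUPS == "anthropogenic"]
  hab <- names(COVARIATE_GROUPS)[COVARIATE_GROUPS == "habitat"]
  s_anth <- suppressMessages(grouping_scores(as_coef_set(tru), subset = anth))
  s_hab <- suppressMessages(grouping_scores(as_coef_set(tru), subset = hab))
  expect_gt(s_anth[["among_herd"]], 0)
  expect_equal(unname(s_hab[["among_herd"]]), 0)

  d <- make_beta_grid(c("A", "B"), style = "distinct")
  vecs <- split(d$beta, paste(d$herd, d$season, d$strategy))
  expect_equal(anyDuplicated(vecs), 0)
})
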