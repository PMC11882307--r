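# Shared fixtures, built once per test run. Small sizes: a 20 x 20 km
# landscape and a 16-animal two-herd population with 4-h fixes.

fixture_env <- new.env(parent = emptyenv())

tiny_stack <- function() {
  if (is.null(fixture_env$stack)) {
    fixture_env$stack <- make_landscape(n_rows = 80, n_cols = 80,
                                        cell_size = 250, seed = 7)
  }
  fixture_env$stack
}

tiny_scenario <- function(...) {
  make_scenario(
    herds = data.frame(herd = c("A", "B"), n = c(4, 4),
                       migrant_prop = c(0.5, 0.5)),
    fix_interval_h = 4, sep_km = 10, range_radius = 2000,
    landscape = tiny_stack(), ...
  )
}

tiny_pop <- function() {
  if (is.null(fixture_env$pop)) {
    fixture_env$pop <- simulate_population(tiny_scenario(), seed = 11)
  }
  fixture_env$pop
}

tiny_calls <- function() {
  if (is.null(fixture_env$calls)) {
    fixture_env$calls <- classify_population(tiny_pop()$fixes)
  }
  fixture_env$calls
}

# a complete herd x season x strategy x covariate grid with given betas
coef_grid <- function(herds = c("A", "B"), covariates = c("k1", "k2"),
                      beta = 0, se = 0.1) {
  g <- expand.grid(herd = herds, season = c("winter", "summer"),
                   strategy = c("migrant", "resident"),
                   covariate = covariates, stringsAsFactors = FALSE)
  g$beta <- rep_len(beta, nrow(g))
  g$se <- rep_len(se, nrow(g))
  as_coef_set(g)
}

# design-level used/available generator: used points thinned among K
# uniform-disc candidates by exp(beta'z); availability uniform on the disc.
# Bypasses trajectories for fast estimator tests.
design_sim <- function(stack, beta, n_strata = 6, n_used = 300,
                       n_avail = 1500, radius = 2000, K = 30, seed = 1) {
  set.seed(seed)
  ext_x <- stack$n_cols * stack$cell_size
  ext_y <- stack$n_rows * stack$cell_size
  tabs <- vector("list", n_strata)
  for (s in seq_len(n_strata)) {
    cx <- stats::runif(1, radius + 500, ext_x - radius - 500)
    cy <- stats::runif(1, radius + 500, ext_y - radius - 500)
    days <- sample(30:90, n_used, replace = TRUE)
    r <- radius * sqrt(stats::runif(n_used * K))
    a <- stats::runif(n_used * K, 0, 2 * pi)
    px <- matrix(cx + r * cos(a), n_used, K)
    py <- matrix(cy + r * sin(a), n_used, K)
    cov <- extract_covariates(stack, as.vector(px), as.vector(py),
                              rep(days, K))
    eta <- matrix(design_matrix_natural(cov) %*% beta, n_used, K)
    pick <- vapply(seq_len(n_used), function(i) {
      w <- exp(eta[i, ] - max(eta[i, ]))
      sample.int(K, 1, prob = w)
    }, integer(1))
    used <- data.frame(x = px[cbind(seq_len(n_used), pick)],
                       y = py[cbind(seq_len(n_used), pick)],
                       day = days, stratum = paste0("s", s))
    ra <- radius * sqrt(stats::runif(n_avail))
    aa <- stats::runif(n_avail, 0, 2 * pi)
    avail <- data.frame(x = cx + ra * cos(aa), y = cy + ra * sin(aa),
                        day = sample(days, n_avail, replace = TRUE),
                        stratum = paste0("s", s))
    tabs[[s]] <- extract_design(used, avail, stack)
  }
  preprocess_design(do.call(rbind, tabs))
}
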