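test_that("reference bandwidth matches its closed form and equivariances", {
  set.seed(1)
  x <- rnorm(64)
  x <- (x - mean(x)) / sd(x) * 1000          # var exactly 1e6
  y <- rnorm(64)
  y <- (y - mean(y)) / sd(y) * 1000
  pts <- data.frame(x = x, y = y)
  expect_equal(reference_bandwidth(pts), 1000 * 64^(-1 / 6))
  expect_equal(reference_bandwidth(pts), 500)  # 64^(1/6) = 2

  # scale equivariance and order invariance
  expect_equal(reference_bandwidth(pts * 2), 2 * reference_bandwidth(pts))
  expect_equal(reference_bandwidth(pts[sample(64), ]),
               reference_bandwidth(pts))

  expect_error(reference_bandwidth(pts[1:4, ]), "at least 5")
  expect_error(reference_bandwidth(data.frame(x = rep(1, 9),
                                              y = rep(2, 9))), "identical")
})

test_that("kernel density conserves mass and rejects clipped grids", {
  set.seed(2)
  pts <- data.frame(x = rnorm(400, 0, 800), y = rnorm(400, 0, 800))
  ud <- kde_density(pts)
  expect_equal(sum(ud$density) * ud$cell_size^2, 1, tolerance = 1e-9)
  expect_true(all(ud$density >= 0))
  expect_error(kde_density(pts, margin_h = 0.3), "clipped")
})

test_that("a single-point KDE peaks at its cell, radially symmetric", {
  # point sits exactly on a cell center
  pts <- data.frame(x = rep(550, 6), y = rep(550, 6))
  ud <- kde_density(pts, h = 300,
                    grid = list(origin = c(-2000, -2000), cell_size = 100,
                                n_rows = 50, n_cols = 50))
  peak <- which(ud$density == max(ud$density), arr.ind = TRUE)
  px <- ud$origin[1] + (peak[1, 2] - 0.5) * ud$cell_size
  py <- ud$origin[2] + (peak[1, 1] - 0.5) * ud$cell_size
  expect_equal(unname(c(px, py)), c(550, 550))
  # radial symmetry: equal offsets give equal densities
  d1 <- ud$density[peak[1, 1] + 5, peak[1, 2]]
  d2 <- ud$density[peak[1, 1] - 5, peak[1, 2]]
  d3 <- ud$density[peak[1, 1], peak[1, 2] + 5]
  expect_equal(d1, d2, tolerance = 1e-6)
  expect_equal(d1, d3, tolerance = 1e-6)
})

test_that("two distant clusters split the mass evenly", {
  pts <- data.frame(x = c(rep(0, 50), rep(20000, 50)),
                    y = rep(0, 100))
  ud <- kde_density(pts, h = 500)
  xc <- ud$origin[1] + (seq_len(ud$n_cols) - 0.5) * ud$cell_size
  left <- sum(ud$density[, xc < 10000]) * ud$cell_size^2
  expect_equal(left, 0.5, tolerance = 0.01)
})

test_that("KDE mode tracks the sample mean on a Gaussian cloud", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- data.frame(x = rnorm(2000, 5000, 1000),
                      y = rnorm(2000, 7000, 1000))
    ud <- kde_density(pts, h = 1000,
                      grid = list(origin = c(mean(pts$x) - 5000,
                                             mean(pts$y) - 5000),
                                  cell_size = 50, n_rows = 200,
                                  n_cols = 200))
    peak <- which(ud$density == max(ud$density), arr.ind = TRUE)[1, ]
    px <- ud$origin[1] + (peak[2] - 0.5) * ud$cell_size
    py <- ud$origin[2] + (peak[1] - 0.5) * ud$cell_size
    expect_lt(sqrt((px - mean(pts$x))^2 + (py - mean(pts$y))^2), 100)
  }
})

test_that("isopleths are minimal prefixes with documented tie-breaking", {
  # uniform density over k cells: the mask takes ceiling(level * k) cells
  k <- 40
  ud <- structure(list(origin = c(0, 0), cell_size = 100, n_rows = 4,
                       n_cols = 10,
                       density = matrix(1 / (k * 100^2), 4, 10),
                       h = 100, n = 1), class = "ud_grid")
  iso <- isopleth(ud, level = 0.95)
  expect_equal(sum(iso$mask), ceiling(0.95 * k))
  # ties broken in cell storage order: excluded cells are the last ones
  expect_equal(which(!iso$mask), seq_len(k - ceiling(0.95 * k)) + 38)

  expect_error(isopleth(ud, level = 0), "between 0 and 1")
  expect_error(isopleth(ud, level = 1), "between 0 and 1")

  # near-1 level covers essentially the whole support
  iso99 <- isopleth(ud, level = 1 - 1e-9)
  expect_equal(sum(iso99$mask), k)
})

test_that("isopleth masks nest across levels and translate with the data", {
  set.seed(4)
  pts <- data.frame(x = rnorm(500, 0, 700), y = rnorm(500, 0, 700))
  ud <- kde_density(pts, h = 400)
  m50 <- isopleth(ud, 0.5)$mask
  m95 <- isopleth(ud, 0.95)$mask
  expect_true(all(m95[m50]))

  shift <- pts
  shift$x <- shift$x + 5000
  ud2 <- kde_density(shift, h = 400)
  expect_equal(ud2$density, ud$density, tolerance = 1e-9)
  expect_equal(ud2$origin[1], ud$origin[1] + 5000)
})

test_that("the 95% isopleth covers ~95% of a Gaussian sample", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- data.frame(x = rnorm(5000, 0, 1000), y = rnorm(5000, 0, 1000))
    rng <- delineate_range(pts, id = "g", season = "winter", year = 1)
    ud <- rng$ud
    rc <- cbind(floor((pts$y - ud$origin[2]) / ud$cell_size) + 1,
                floor((pts$x - ud$origin[1]) / ud$cell_size) + 1)
    inside <- rng$mask[rc]
    expect_gte(mean(inside), 0.93)
    expect_lte(mean(inside), 0.97)
  }
})

test_that("utilization densities export as readable ASCII grids", {
  set.seed(7)
  pts <- data.frame(x = rnorm(100, 0, 400), y = rnorm(100, 0, 400))
  rng <- delineate_range(pts, id = "u1", season = "winter", year = 1)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ud_asc(rng, p)
  lines <- readLines(p)
  expect_equal(lines[1], paste("ncols", rng$ud$n_cols))
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  expect_equal(sum(vals) * rng$ud$cell_size^2, 1, tolerance = 1e-4)
})

test_that("isopleth GeoJSON export is valid and carries metadata", {
  set.seed(5)
  pts <- data.frame(x = rnorm(200, 0, 500), y = rnorm(200, 0, 500))
  rng <- delineate_range(pts, id = "a1", season = "summer", year = 1)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_isopleth_geojson(rng, p)
  gj <- jsonlite::read_json(p)
  expect_equal(gj$type, "Feature")
  expect_equal(gj$geometry$type, "MultiPolygon")
  expect_equal(gj$properties$animal_id, "a1")
  expect_equal(length(gj$geometry$coordinates), sum(rng$mask))
})
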