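test_that("coordinates are reproducible, in-bounds and distinct", {
  a <- sim_coordinates(50, c(300, 350), seed = 4)
  b <- sim_coordinates(50, c(300, 350), seed = 4)
  expect_identical(a, b)
  expect_true(all(a$x_km >= 0 & a$x_km <= 300))
  expect_true(all(a$y_km >= 0 & a$y_km <= 350))
  expect_equal(anyDuplicated(a[, c("x_km", "y_km")]), 0L)
  expect_error(sim_coordinates(5), "at least 10")
  expect_error(sim_coordinates(20, c(0, 100)), "extent")
})

test_that("IDW interpolation honours exact hits, symmetry and the NN limit", {
  st <- rbind(c(0, 0), c(10, 0))
  vals <- c(20, 24)
  expect_equal(idw_interpolate(st, vals, rbind(c(0, 0))), 20)
  expect_equal(idw_interpolate(st, vals, rbind(c(5, 0))), 22)
  # high power approaches nearest-neighbour
  got <- idw_interpolate(st, vals, rbind(c(2, 1)), power = 8)
  expect_lt(abs(got - 20), 0.01)
  expect_error(idw_interpolate(st[0, , drop = FALSE], numeric(0),
                               rbind(c(1, 1))), "at least one station")
  expect_error(idw_interpolate(st, vals, rbind(c(1, 1)), power = 0),
               "positive")
})

test_that("zero gradient and zero noise give a flat temperature field", {
  cfg <- sim_config(n_sites = 20, n_stations = 5,
                    temp = list(base = c(mayT = 16.5, junT = 23.5,
                                         julT = 24.5, augT = 23.5),
                                slope_x = 0, slope_y = 0, station_sd = 0))
  coords <- sim_coordinates(20, cfg$extent, seed = 1)
  env <- sim_environment(coords, cfg, seed = 2)
  expect_equal(env$junT, rep(23.5, 20), tolerance = 1e-10)
})

test_that("distance covariate is zero at the source location", {
  cfg <- sim_config(n_sites = 20)
  coords <- sim_coordinates(20, cfg$extent, seed = 3)
  coords$x_km[1] <- cfg$source[[1]]
  coords$y_km[1] <- cfg$source[[2]]
  env <- sim_environment(coords, cfg, seed = 4)
  expect_equal(env$dist_km[1], 0)
})

test_that("land-use proportions are valid compositions at every scale", {
  cfg <- sim_config(n_sites = 40)
  coords <- sim_coordinates(40, cfg$extent, seed = 5)
  env <- sim_environment(coords, cfg, seed = 6)
  for (sc in cfg$landuse$scales) {
    cols <- paste0(cfg$landuse$classes, sc)
    block <- as.matrix(env[, cols])
    expect_true(all(block >= 0 & block <= 1))
    expect_true(all(rowSums(block) <= 1))
  }
})

test_that("June temperature is spatially autocorrelated on the Gabriel graph", {
  cfg <- sim_config(n_sites = 60)
  for (seed in 1:5) {
    coords <- sim_coordinates(60, cfg$extent, seed = seed)
    env <- sim_environment(coords, cfg, seed = seed + 100)
    g <- gabriel_graph(coords, coords = c("x_km", "y_km"), id = "site_id")
    expect_gt(morans_i(env$junT, g), 0)
  }
})

test_that("the invasive species is absent above the thermal cutoff", {
  cfg <- sim_config(n_sites = 200)
  d <- sim_site_table(cfg, seed = 9)
  hot <- d$sites$junT > cfg$species$hhalys$cutoff
  expect_gt(sum(hot), 0)          # the gradient must cross the cutoff
  expect_true(all(d$sites$hhalys[hot] == 0))
  # below the cutoff abundance declines with June temperature
  cold <- !hot
  expect_lt(stats::cor(d$sites$junT[cold], d$sites$hhalys[cold],
                       method = "spearman"), 0)
})

test_that("identical generating laws give exchangeable species counts", {
  cfg <- sim_config(n_sites = 300, species = list(
    sp1 = list(intercept = 1.5),
    sp2 = list(intercept = 1.5),
    sp3 = list(intercept = 1.5)))
  coords <- sim_coordinates(300, cfg$extent, seed = 10)
  env <- sim_environment(coords, cfg, seed = 11)
  ab <- sim_abundance(env, coords, cfg, seed = 12)
  ks <- suppressWarnings(
    stats::ks.test(ab$counts$sp1, ab$counts$sp2))
  expect_gt(ks$p.value, 0.01)
})

test_that("a log-linear fit recovers the June-temperature coefficient", {
  cfg <- sim_config()
  truth <- cfg$species$hhalys$junT
  est <- vapply(1:10, function(seed) {
    d <- sim_site_table(cfg, seed = seed)
    s <- d$sites[d$sites$junT <= cfg$species$hhalys$cutoff, ]
    fit <- stats::glm(
      hhalys ~ junT + I(dist_km / 100) + developopen250 + forestdeci250,
      family = stats::poisson(), data = s)
    unname(stats::coef(fit)["junT"])
  }, numeric(1))
  expect_true(all(est < 0))                       # sign recovered every seed
  expect_lt(abs(median(est) - truth) / abs(truth), 0.25)
})

test_that("dataset assembly is seed-stable and matches the configured shape", {
  d <- sim_site_table(sim_config(n_sites = 40), seed = 21)
  expect_equal(nrow(d$sites), 40)
  expect_true(all(c("hhalys", "chilaris", "eservus") %in% names(d$sites)))
  expect_true(all(rowSums(d$sites[, c("hhalys", "chilaris", "eservus")]) > 0))
  expect_equal(d$truth$master_seed, 21)
  expect_identical(d$truth$species$hhalys$cutoff, 23.5)

  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "run1")
  p2 <- file.path(dir, "run2")
  sim_site_table(sim_config(n_sites = 40), seed = 21, path = p1)
  sim_site_table(sim_config(n_sites = 40), seed = 21, path = p2)
  expect_identical(readLines(paste0(p1, ".csv")),
                   readLines(paste0(p2, ".csv")))
})

test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(n_sites = 5), "at least 10")
  expect_error(sim_config(dispersion = 0), "positive")
  expect_error(sim_config(extent = c(-1, 10)), "positive lengths")
  expect_error(
    sim_config(temp = list(base = c(mayT = 16.5, junT = 30,
                                    julT = 24.5, augT = 23.5),
                           slope_x = 0.01, slope_y = 0, station_sd = 0.3)),
    "cutoff")
})
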