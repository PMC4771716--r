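#' Configuration for the synthetic survey generator
#'
#' Defaults emulate a regional multi-year sweep-net survey of soybean
#' fields: 329 sites over a 300 x 350 km rectangle, monthly (May-August)
#' temperature surfaces interpolated by inverse-distance weighting from 50
#' synthetic weather stations riding an east-west regional gradient,
#' compositional land-use covariates for five classes at seven buffer scales
#' (250 m to 10 km), Euclidean distance from an invasion source near the
#' western edge, and negative-binomial counts for three species: one
#' invasive whose expected abundance falls with June temperature and is
#' forced to zero above a hard 23.5 degree Celsius threshold, and two
#' natives that increase with July temperature and forest cover.
#'
#' @param n_sites Number of sampled fields (>= 10).
#' @param extent c(width, height) of the study rectangle in km.
#' @param n_stations Number of synthetic weather stations.
#' @param idw_power Inverse-distance weighting power (> 0).
#' @param temp List: `base` named monthly intercepts (deg C at the western
#'   edge), `slope_x`/`slope_y` regional gradient (deg C per km),
#'   `station_sd` station-level noise sd.
#' @param landuse List: `classes`, `scales` (column suffixes), per-class
#'   logit `intercept` and spatial slopes `bx`, `by` (against an implicit
#'   "other" baseline), `shared_sd` (latent site effect common to all
#'   scales), `scale_sd` (scale-specific noise).
#' @param source c(x, y) location of the invasion source (km).
#' @param species Named list of per-species response parameters; see the
#'   default for the expected fields (`intercept` and coefficient list on
#'   the log scale; the invasive carries `cutoff` in deg C and
#'   `cutoff_type` `"hard"` or `"logistic"`).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 329,
                       extent = c(300, 350),
                       n_stations = 50,
                       idw_power = 2,
                       temp = list(
                         base = c(mayT = 16.5, junT = 21.5,
                                  julT = 24.5, augT = 23.5),
                         slope_x = 0.01, slope_y = 0, station_sd = 0.3),
                       landuse = list(
                         classes = c("forestdeci", "forestever", "forestother",
                                     "developopen", "cropscornsoy"),
                         scales = c("250", "500", "1k", "2k", "3k", "5k", "10k"),
                         intercept = c(-0.6, -1.2, -1.4, -1.0, -0.2),
                         bx = c(-0.8, -0.5, 0.4, 0.6, 0.5),
                         by = c(0.5, -0.4, 0.3, -0.5, 0.2),
                         shared_sd = 0.5, scale_sd = 0.3),
                       source = c(x = 15, y = 175),
                       species = list(
                         hhalys = list(
                           intercept = 3.0,
                           junT = -0.8, junT_ref = 22.5,
                           dist = -0.4,
                           developopen250 = 3.0, forestdeci250 = 2.0,
                           cutoff = 23.5, cutoff_type = "hard",
                           cutoff_rate = 8),
                         chilaris = list(
                           intercept = 1.5, julT = 0.5, julT_ref = 26,
                           forest500 = 2.0),
                         eservus = list(
                           intercept = 1.8, julT = 0.4, julT_ref = 26,
                           forest500 = 1.5)),
                       dispersion = 1.5) {
  cfg <- list(n_sites = n_sites, extent = extent, n_stations = n_stations,
              idw_power = idw_power, temp = temp, landuse = landuse,
              source = source, species = species, dispersion = dispersion)
  if (n_sites < 10) abort("`n_sites` must be at least 10")
  if (length(extent) != 2 || any(extent <= 0)) {
    abort("`extent` must be two positive lengths (km)")
  }
  if (n_stations < 1) abort("`n_stations` must be at least 1")
  if (idw_power <= 0) abort("`idw_power` must be positive")
  if (dispersion <= 0) abort("`dispersion` must be positive")
  inv <- species$hhalys
  if (!is.null(inv$cutoff)) {
    tmin <- temp$base[["junT"]]
    tmax <- tmin + abs(temp$slope_x) * extent[1] + abs(temp$slope_y) * extent[2]
    if (inv$cutoff < min(tmin, tmax) || inv$cutoff > max(tmin, tmax)) {
      abort(sprintf(
        "invasive thermal cutoff (%.1f) lies outside the generated June temperature range [%.1f, %.1f]",
        inv$cutoff, min(tmin, tmax), max(tmin, tmax)))
    }
  }
  structure(cfg, class = "sim_config")
}

#' Draw site coordinates uniformly over the study rectangle
#'
#' @param n Number of sites (>= 10).
#' @param extent c(width, height) in km.
#' @param seed RNG seed.
#' @return A tibble with `site_id`, `x_km`, `y_km`; coordinates are
#'   pairwise distinct.
#' @export
sim_coordinates <- function(n = 329, extent = c(300, 350), seed = NULL) {
  if (n < 10) abort("`n` must be at least 10")
  if (length(extent) != 2 || any(extent <= 0)) abort("degenerate extent")
  with_seed(seed, {
    xy <- cbind(runif(n, 0, extent[1]), runif(n, 0, extent[2]))
    while (anyDuplicated(xy)) {   # astronomically rare; redraw duplicates
      dup <- duplicated(xy)
      xy[dup, ] <- cbind(runif(sum(dup), 0, extent[1]),
                         runif(sum(dup), 0, extent[2]))
    }
    tibble::tibble(site_id = sprintf("s%03d", seq_len(n)),
                   x_km = xy[, 1], y_km = xy[, 2])
  })
}

#' Inverse-distance-weighted interpolation
#'
#' Value at a target is the weighted mean of station values with weights
#' \eqn{d^{-p}}. A target coincident with a station returns that station's
#' value exactly.
#'
#' @param station_xy Stations x 2 coordinate matrix.
#' @param station_values Numeric vector, one value per station.
#' @param target_xy Targets x 2 coordinate matrix.
#' @param power Positive IDW exponent (2 by default; large values approach
#'   nearest-neighbour interpolation).
#' @return Numeric vector of interpolated values, one per target row.
#' @export
idw_interpolate <- function(station_xy, station_values, target_xy, power = 2) {
  station_xy <- as.matrix(station_xy)
  target_xy <- as.matrix(target_xy)
  if (nrow(station_xy) < 1) abort("at least one station is required")
  if (length(station_values) != nrow(station_xy)) {
    abort("`station_values` must have one value per station")
  }
  if (power <= 0) abort("`power` must be positive")
  d2 <- outer(rowSums(target_xy^2), rep(1, nrow(station_xy))) +
    outer(rep(1, nrow(target_xy)), rowSums(station_xy^2)) -
    2 * tcrossprod(target_xy, station_xy)
  d <- sqrt(pmax(d2, 0))
  vapply(seq_len(nrow(target_xy)), function(i) {
    di <- d[i, ]
    hit <- which(di == 0)
    if (length(hit) > 0) return(station_values[hit[1]])
    w <- di^(-power)
    sum(w * station_values) / sum(w)
  }, numeric(1))
}

#' Generate environmental covariates at the sites
#'
#' Monthly temperatures are a linear regional gradient evaluated at random
#' station locations, perturbed by station noise, then interpolated to the
#' sites by IDW - so the site-level surface is spatially smooth (positively
#' autocorrelated) with local station-driven texture. Land-use proportions
#' come from a logistic-normal model: each class has a spatially smooth
#' logit mean (linear trend plus a site-level latent effect shared across
#' buffer scales) plus scale-specific noise, mapped through a softmax with
#' an implicit "other" baseline so that the five class proportions at each
#' scale are in (0, 1) and sum to less than 1. Distance is Euclidean from
#' the configured source.
#'
#' @param coords A [sim_coordinates()] tibble.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return A tibble with columns `mayT`..`augT`, `<class><scale>` land-use
#'   proportions, and `dist_km`.
#' @export
sim_environment <- function(coords, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  xy <- as.matrix(coords[, c("x_km", "y_km")])
  n <- nrow(xy)
  tp <- config$temp
  lu <- config$landuse
  with_seed(seed, {
    st_xy <- cbind(runif(config$n_stations, 0, config$extent[1]),
                   runif(config$n_stations, 0, config$extent[2]))
    temps <- sapply(names(tp$base), function(mon) {
      st_val <- tp$base[[mon]] + tp$slope_x * st_xy[, 1] +
        tp$slope_y * st_xy[, 2] + rnorm(config$n_stations, 0, tp$station_sd)
      idw_interpolate(st_xy, st_val, xy, config$idw_power)
    })
    colnames(temps) <- names(tp$base)

    xs <- xy[, 1] / config$extent[1]
    ys <- xy[, 2] / config$extent[2]
    k <- length(lu$classes)
    shared <- matrix(rnorm(n * k, 0, lu$shared_sd), n, k)
    lu_cols <- list()
    for (s in seq_along(lu$scales)) {
      eta <- sapply(seq_len(k), function(c_i) {
        lu$intercept[c_i] + lu$bx[c_i] * xs + lu$by[c_i] * ys +
          shared[, c_i] + rnorm(n, 0, lu$scale_sd)
      })
      expd <- exp(cbind(eta, 0))         # last column: "other" baseline
      prop <- expd / rowSums(expd)
      for (c_i in seq_len(k)) {
        lu_cols[[paste0(lu$classes[c_i], lu$scales[s])]] <- prop[, c_i]
      }
    }

    dist_km <- sqrt((xy[, 1] - config$source[[1]])^2 +
                    (xy[, 2] - config$source[[2]])^2)
    dplyr::bind_cols(tibble::as_tibble(temps),
                     tibble::as_tibble(lu_cols),
                     tibble::tibble(dist_km = dist_km))
  })
}

# Per-species log expected count from environment; returns list(mu, beta)
# where beta records the realised coefficient set for the truth bundle.
species_mu <- function(sp, name, env, dispersion) {
  lp <- rep(sp$intercept, nrow(env))
  beta <- list(intercept = sp$intercept)
  if (!is.null(sp$junT)) {
    lp <- lp + sp$junT * (env$junT - sp$junT_ref)
    beta$junT <- sp$junT
  }
  if (!is.null(sp$julT)) {
    lp <- lp + sp$julT * (env$julT - sp$julT_ref)
    beta$julT <- sp$julT
  }
  if (!is.null(sp$dist)) {
    lp <- lp + sp$dist * env$dist_km / 100
    beta$dist_per_100km <- sp$dist
  }
  for (v in c("developopen250", "forestdeci250")) {
    if (!is.null(sp[[v]])) {
      lp <- lp + sp[[v]] * env[[v]]
      beta[[v]] <- sp[[v]]
    }
  }
  if (!is.null(sp$forest500)) {
    lp <- lp + sp$forest500 * (env$forestdeci500 + env$forestever500)
    beta$forest500 <- sp$forest500
  }
  mu <- exp(lp)
  if (!is.null(sp$cutoff)) {
    beta$cutoff <- sp$cutoff
    beta$cutoff_type <- sp$cutoff_type
    if (identical(sp$cutoff_type, "hard")) {
      mu <- mu * as.numeric(env$junT <= sp$cutoff)
    } else {
      mu <- mu / (1 + exp(sp$cutoff_rate * (env$junT - sp$cutoff)))
    }
  }
  list(mu = mu, beta = beta)
}

#' Generate species counts and the generating truth
#'
#' Counts are negative binomial with a log-linear mean in the environmental
#' covariates. The invasive species' mean is multiplied by zero wherever
#' June temperature exceeds the configured cutoff (hard thermal limit;
#' a steep logistic decline is available via `cutoff_type = "logistic"`).
#' Native species carry positive July-temperature and forest-cover
#' coefficients. Sites where all species would be absent are redrawn so
#' every surveyed field has at least one capture (the community transforms
#' require positive site totals); this conditioning is part of the emulated
#' survey design.
#'
#' @param env A [sim_environment()] tibble.
#' @param coords Matching [sim_coordinates()] tibble.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return A list with `counts` (tibble, one column per species) and
#'   `truth` (per-species coefficients and the generator's structural
#'   facts, serialisable as JSON).
#' @export
sim_abundance <- function(env, coords, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(env)
  with_seed(seed, {
    mus <- list()
    truth <- list()
    for (nm in names(config$species)) {
      sm <- species_mu(config$species[[nm]], nm, env, config$dispersion)
      mus[[nm]] <- sm$mu
      truth[[nm]] <- sm$beta
    }
    counts <- lapply(mus, function(mu) rnbinom(n, size = config$dispersion, mu = mu))
    cmat <- do.call(cbind, counts)
    for (tries in seq_len(100)) {
      zero <- rowSums(cmat) == 0
      if (!any(zero)) break
      for (j in seq_along(mus)) {
        cmat[zero, j] <- rnbinom(sum(zero), size = config$dispersion,
                                 mu = mus[[j]][zero])
      }
    }
    if (any(rowSums(cmat) == 0)) {
      # last resort: one individual of the most likely species
      zero <- which(rowSums(cmat) == 0)
      best <- max.col(do.call(cbind, mus)[zero, , drop = FALSE])
      cmat[cbind(zero, best)] <- 1L
    }
    colnames(cmat) <- names(mus)
    list(
      counts = tibble::as_tibble(cmat),
      truth = list(species = truth, dispersion = config$dispersion,
                   true_scale = "very broad", seed = seed)
    )
  })
}

#' Generate a complete synthetic site table
#'
#' Bundles coordinates, environment and abundances into the single input
#' table the analysis pipeline consumes, together with the generating truth
#' for recovery tests. Stage seeds are derived deterministically from the
#' one master seed, so the same seed always yields a byte-identical table.
#'
#' @param config A [sim_config()].
#' @param seed Master RNG seed.
#' @param path Optional basename: writes `<path>.csv` (site table) and
#'   `<path>_truth.json`.
#' @return A list with `sites` (tibble: site_id, coordinates, environment,
#'   species counts) and `truth`.
#' @examples
#' d <- sim_site_table(sim_config(n_sites = 40), seed = 1)
#' dplyr::glimpse(d$sites[1:6])
#' @export
sim_site_table <- function(config = sim_config(), seed = 1, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(seed, 3)
  coords <- sim_coordinates(config$n_sites, config$extent, seeds[1])
  env <- sim_environment(coords, config, seeds[2])
  ab <- sim_abundance(env, coords, config, seeds[3])
  sites <- dplyr::bind_cols(coords, env, ab$counts)
  truth <- ab$truth
  truth$master_seed <- seed
  if (!is.null(path)) {
    csv <- paste0(path, ".csv")
    ok <- tryCatch({
      readr::write_csv(sites, csv)
      jsonlite::write_json(truth, paste0(path, "_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      TRUE
    }, error = function(e) {
      abort(sprintf("failed writing dataset to '%s': %s", path, conditionMessage(e)))
    })
  }
  list(sites = sites, truth = truth)
}
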