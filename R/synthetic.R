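# Self-contained synthetic world: dissected-ravine terrain, NLCD-like land
# cover, soils, climate, roads, protected areas, urbanization probability,
# watersheds, and occurrence samples drawn from a known suitability truth.
# One master seed fans out to per-layer substreams so layers can be
# regenerated independently.

#' Configuration of the synthetic world
#'
#' Defaults describe a 24 x 24 km landscape at 60-m cells where steep,
#' low-lying carved ravines wind through a gently sloping sandy upland
#' matrix: the setting the pipeline is built for.  Occurrence defaults
#' mirror the modeled species' data: 211 records, about 60% nymphs, and
#' roughly 30% of records within 100 m of a road.
#'
#' @param size grid edge in cells (default 400).
#' @param cell_size cell size in meters (default 60).
#' @param n_ravines number of incised ravine systems.
#' @param ravine_depth maximum incision depth (m).
#' @param n_roads number of random road polylines.
#' @param protected_frac target protected-area fraction.
#' @param n_occurrences raw occurrence records to sample.
#' @param nymph_frac fraction labeled nymph.
#' @param road_bias target fraction of records within 100 m of roads.
#' @param beta true suitability coefficients: intercept, slope (deg), tpi
#'   (m), pct_agriculture (%), temp (deg C).
#' @param seed master RNG seed (mandatory).
#' @return a `wd_config` list.
#' @export
world_config <- function(size = 400, cell_size = 60, n_ravines = 25,
                         ravine_depth = 24, n_roads = 14,
                         protected_frac = 0.20, n_occurrences = 211,
                         nymph_frac = 0.6, road_bias = 0.30,
                         beta = c(intercept = -6, slope = 0.9, tpi = -0.35,
                                  pct_agriculture = -0.06, temp = 0.15),
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "wd_config")
}

# smoothed gaussian random field on an n x n grid
smooth_field <- function(n, cs, sd = 1, radius = 240, passes = 2, seed = 1) {
  g <- grid_create(matrix(with_seed(seed, stats::rnorm(n * n, 0, sd)), n, n),
                   cs)
  for (i in seq_len(passes)) g <- focal_stat(g, radius, "mean")
  g
}

# Bresenham-style rasterization of a segment in cell coordinates
trace_line <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  cbind(round(seq(r0, r1, length.out = n)),
        round(seq(c0, c1, length.out = n)))
}

#' Generate the complete synthetic world
#'
#' Builds, on one shared geometry: a DEM (regional south-dipping gradient
#' plus smoothed noise, minus dendritic ravines carved along downhill random
#' walks), a 15-class land cover driven by elevation and ravine context
#' (woody wetlands on ravine floors, evergreen on the walls), canopy, three
#' soil fields, two climate fields, random road polylines, protected-area
#' blobs near the target fraction, pour-point watersheds, a
#' development-probability surface decaying from the developed blobs, and a
#' 3-band region grid.  Bookkeeping (carved cells, the true suitability
#' surface) is retained for recovery tests.
#'
#' @param cfg a `wd_config`.
#' @return an `rh_world` list of layers plus `truth`.
#' @export
generate_world <- function(cfg) {
  n <- cfg$size; cs <- cfg$cell_size
  lg <- lc_legend()
  seeds <- vapply(1:12, function(k) fan_seed(cfg$seed, k), 0)

  # --- terrain ------------------------------------------------------------
  base <- outer(seq_len(n), seq_len(n), function(i, j)
    60 - 40 * i / n + 6 * j / n)
  noise <- smooth_field(n, cs, sd = 25, radius = 3 * cs, passes = 2,
                        seed = seeds[1])$values
  dem0 <- base + noise
  carved <- matrix(FALSE, n, n)
  depth <- matrix(0, n, n)
  with_seed(seeds[2], {
    springs <- cbind(sample(round(n * 0.05):round(n * 0.6), cfg$n_ravines,
                            replace = TRUE),
                     sample(seq_len(n), cfg$n_ravines, replace = TRUE))
    for (k in seq_len(cfg$n_ravines)) {
      r <- springs[k, 1]; cc <- springs[k, 2]
      path <- matrix(c(r, cc), 1, 2)
      visited <- matrix(FALSE, n, n); visited[r, cc] <- TRUE
      for (step in seq_len(3 * n)) {
        # downhill-biased meandering walk (never revisits its own course,
        # drifts with the regional south-dipping gradient)
        nb <- cbind(r + D8_OFFSETS[, 1], cc + D8_OFFSETS[, 2])
        ok <- nb[, 1] >= 1 & nb[, 1] <= n & nb[, 2] >= 1 & nb[, 2] <= n
        ok[ok] <- !visited[nb[ok, , drop = FALSE]]
        if (!any(ok)) break
        nb <- nb[ok, , drop = FALSE]
        z <- dem0[nb] + stats::rnorm(nrow(nb), 0, 0.8) -
          0.15 * (nb[, 1] - r)           # southward drift
        pick <- nb[which.min(z), ]
        if (dem0[pick[1], pick[2]] > dem0[r, cc] + 4) break
        r <- pick[1]; cc <- pick[2]
        visited[r, cc] <- TRUE
        path <- rbind(path, c(r, cc))
        if (r == 1 || r == n || cc == 1 || cc == n) break
        if (carved[r, cc]) break   # joined an existing ravine: dendritic
      }
      if (nrow(path) < 8) next
      dpth <- seq(2, cfg$ravine_depth, length.out = nrow(path))
      for (i in seq_len(nrow(path))) {
        depth[path[i, 1], path[i, 2]] <- max(depth[path[i, 1], path[i, 2]],
                                             dpth[i])
      }
      carved[path] <- TRUE
    }
  })
  # widen the incision into a V cross-section: depth decays with distance
  if (any(carved)) {
    d_carve <- sqrt(edt_sq(carved)) * cs
    peak <- matrix(0, n, n)
    peak[carved] <- depth[carved]
    # nearest-carved-cell depth, spread by a short smoothing pass
    spread <- focal_stat(grid_create(peak, cs), 2 * cs, "mean")$values
    spread <- spread * (max(depth) / max(spread))
    incision <- pmax(spread * pmax(1 - d_carve / (4 * cs), 0),
                     ifelse(carved, depth, 0))
    dem_v <- dem0 - incision
  } else dem_v <- dem0
  dem <- grid_create(dem_v, cs)

  # --- roads, lakes, developed blobs ---------------------------------------
  roads <- matrix(FALSE, n, n)
  with_seed(seeds[3], {
    for (k in seq_len(cfg$n_roads)) {
      side <- sample(4, 2)
      pt <- function(s) switch(s, c(1, sample(n, 1)), c(n, sample(n, 1)),
                               c(sample(n, 1), 1), c(sample(n, 1), n))
      a <- pt(side[1]); b <- pt(side[2])
      roads[trace_line(a[1], a[2], b[1], b[2])] <- TRUE
    }
  })
  roads_mask <- mask_create(roads, cell_size = cs)
  roads_dist <- distance_to(roads_mask)

  blob <- function(center, radius) {
    rr <- outer(seq_len(n), rep(1, n)) - center[1]
    cc <- outer(rep(1, n), seq_len(n)) - center[2]
    sqrt(rr^2 + cc^2) <= radius
  }
  lakes <- matrix(FALSE, n, n)
  cities <- matrix(FALSE, n, n)
  city_centers <- with_seed(seeds[4], {
    for (k in 1:3) {
      ctr <- c(sample(round(n * 0.6):n, 1), sample(n, 1))  # low-lying south
      lakes <- lakes | blob(ctr, sample(4:8, 1))
    }
    ctrs <- cbind(sample(n, 3), sample(n, 3))
    for (k in 1:3) cities <- cities | blob(ctrs[k, ], sample(10:18, 1))
    ctrs
  })

  # --- land cover ----------------------------------------------------------
  lc <- matrix(lg[["evergreen_forest"]], n, n)
  # land use is clustered at two scales: a fine mosaic plus a coarse
  # (watershed-scale) intensity surface, so agricultural share genuinely
  # varies between subwatersheds
  u_fine <- smooth_field(n, cs, sd = 30, radius = 4 * cs, passes = 2,
                         seed = seeds[5])$values
  u_coarse <- smooth_field(n, cs, sd = 30, radius = max(25, n %/% 12) * cs,
                           passes = 2, seed = seeds[5] + 7)$values
  u <- u_fine / stats::sd(u_fine) + 2 * u_coarse / stats::sd(u_coarse)
  q <- stats::quantile(u, c(0.25, 0.45, 0.6, 0.72, 0.82, 0.9, 0.96))
  lc[u > q[1]] <- lg[["shrub_scrub"]]
  lc[u > q[2]] <- lg[["herbaceous"]]
  lc[u > q[3]] <- lg[["hay_pasture"]]
  lc[u > q[4]] <- lg[["cultivated_crops"]]
  lc[u > q[5]] <- lg[["deciduous_forest"]]
  lc[u > q[6]] <- lg[["mixed_forest"]]
  lc[u > q[7]] <- lg[["barren"]]
  # ravine floors and walls override the upland mosaic
  d_carve_cells <- if (any(carved)) sqrt(edt_sq(carved)) else
    matrix(Inf, n, n)
  lc[d_carve_cells <= 1] <- lg[["woody_wetlands"]]
  lc[d_carve_cells > 1 & d_carve_cells <= 3] <- lg[["evergreen_forest"]]
  emergent <- mask_diff(buffer_mask(mask_create(lakes, cell_size = cs),
                                    2 * cs),
                        mask_create(lakes, cell_size = cs))$member
  lc[emergent] <- lg[["emergent_wetlands"]]
  lc[cities & !lakes] <- lg[["developed_low"]]
  core <- with_seed(seeds[6], cities & blob(city_centers[1, ], 8))
  lc[core & !lakes] <- lg[["developed_medium"]]
  lc[core & blob(city_centers[1, ], 4) & !lakes] <- lg[["developed_high"]]
  ring_dev <- mask_diff(buffer_mask(mask_create(cities, cell_size = cs),
                                    2 * cs),
                        mask_create(cities, cell_size = cs))$member
  lc[ring_dev & !lakes] <- lg[["developed_open"]]
  lc[lakes] <- lg[["open_water"]]
  landcover <- grid_create(lc, cs, kind = "categorical")

  # plantations: blocky subset of upland evergreen away from ravines
  plant <- matrix(FALSE, n, n)
  with_seed(seeds[7], {
    for (k in 1:10) {
      r0 <- sample(n - 20, 1); c0 <- sample(n - 20, 1)
      plant[r0:(r0 + sample(8:20, 1)), c0:(c0 + sample(8:20, 1))] <- TRUE
    }
  })
  plant <- plant & lc == lg[["evergreen_forest"]] & d_carve_cells > 3

  # canopy: dense over forest/wetland, open elsewhere
  canopy_base <- matrix(10, n, n)
  canopy_base[lc %in% c(lg[["evergreen_forest"]], lg[["deciduous_forest"]],
                        lg[["mixed_forest"]], lg[["woody_wetlands"]])] <- 75
  canopy_base[lc == lg[["shrub_scrub"]]] <- 35
  canopy <- grid_create(
    pmin(pmax(canopy_base +
                smooth_field(n, cs, sd = 40, radius = 2 * cs,
                             seed = seeds[8])$values, 0), 100), cs)
  # half the open terrestrial cells stay below the 50% canopy screen by
  # construction; no further adjustment needed

  # --- soils and climate ---------------------------------------------------
  soils <- list(
    conductivity = grid_create(
      pmax(0.8 + smooth_field(n, cs, sd = 6, radius = 3 * cs,
                              seed = seeds[9])$values, 0.05), cs),
    ph = grid_create(pmin(pmax(5.5 + smooth_field(n, cs, sd = 8,
                                                  radius = 3 * cs,
                                                  seed = seeds[9] + 1)$values,
                               3.5), 8), cs),
    pct_sand = grid_create(pmin(pmax(75 + smooth_field(n, cs, sd = 60,
                                                       radius = 3 * cs,
                                                       seed = seeds[9] + 2)$values,
                                     30), 98), cs))
  climate <- list(
    temp_march = grid_create(14 + 4 * outer(seq_len(n), rep(1, n)) / n +
                               smooth_field(n, cs, sd = 3, radius = 4 * cs,
                                            seed = seeds[10])$values, cs),
    precip_march = grid_create(pmax(120 - 30 * outer(rep(1, n),
                                                     seq_len(n)) / n +
                                      smooth_field(n, cs, sd = 30,
                                                   radius = 4 * cs,
                                                   seed = seeds[10] + 1)$values,
                                    40), cs))

  # --- protected areas ------------------------------------------------------
  prot <- matrix(FALSE, n, n)
  with_seed(seeds[11], {
    while (mean(prot) < cfg$protected_frac - 0.005) {
      ctr <- c(sample(n, 1), sample(n, 1))
      prot <- prot | blob(ctr, sample(8:18, 1))
    }
  })
  protected <- mask_create(prot, cell_size = cs)

  # --- hydrology-derived layers --------------------------------------------
  fl <- d8_flow(dem)
  watersheds <- pour_point_watersheds(fl$direction,
                                      blocks = max(5, n %/% 33))
  lf <- geomorphons(dem)

  # development probability decays from existing development
  dev_mask <- mask_create(matrix(lc %in% lc_groups()$developed, n, n),
                          cell_size = cs)
  sleuth_v <- if (any(dev_mask$member)) {
    dd <- distance_to(dev_mask)$values
    p <- round(pmin(100 * exp(-dd / 800), 100), 1)
    p[p < 5] <- 0          # growth is projected adjacent to urban areas only
    p
  } else matrix(0, n, n)
  sleuth_v[lakes] <- 0
  sleuth <- grid_create(sleuth_v, cs)

  regions <- grid_create(
    matrix(rep(c(1L, 2L, 3L), times = c(round(n * 0.45), round(n * 0.45),
                                        n - round(n * 0.45) * 2)),
           n, n, byrow = TRUE), cs, kind = "categorical")

  world <- structure(list(
    config = cfg, dem = dem, landcover = landcover, canopy = canopy,
    soils = soils, climate = climate, roads = roads_mask,
    roads_dist = roads_dist, protected = protected,
    plantations = mask_create(plant, cell_size = cs),
    waterbodies = mask_create(lakes, cell_size = cs),
    watersheds = watersheds, regions = regions, sleuth = sleuth,
    landform = lf, flow = fl,
    truth = list(carved = mask_create(carved, cell_size = cs),
                 incision_depth = depth)),
    class = "rh_world")
  world$truth$suitability <- true_suitability(world, cfg$beta)
  world
}

#' @export
print.rh_world <- function(x, ...) {
  cat(sprintf("<rh_world> %d x %d cells @ %g m (seed %s), %.0f%% protected, %d carved cells\n",
              x$config$size, x$config$size, x$config$cell_size,
              format(x$config$seed), 100 * mean(x$protected$member),
              sum(x$truth$carved$member)))
  invisible(x)
}

# watershed labels: follow D8 to each cell's terminal cell (pointer
# jumping), then group terminals into a blocks x blocks coarse grid
pour_point_watersheds <- function(direction, blocks = 5) {
  dir <- direction$values
  nr <- nrow(dir); nc <- ncol(dir)
  idx <- seq_len(nr * nc)
  r <- ((idx - 1L) %% nr) + 1L; cc <- ((idx - 1L) %/% nr) + 1L
  dd <- dir[idx]
  tr <- r + ifelse(is.na(dd) | dd == 0, 0L, D8_OFFSETS[pmax(dd, 1), 1])
  tc <- cc + ifelse(is.na(dd) | dd == 0, 0L, D8_OFFSETS[pmax(dd, 1), 2])
  off <- tr < 1 | tr > nr | tc < 1 | tc > nc
  tr[off] <- r[off]; tc[off] <- cc[off]
  nxt <- (tc - 1L) * nr + tr
  for (i in seq_len(ceiling(log2(nr * nc)) + 1)) {
    nxt2 <- nxt[nxt]
    if (identical(nxt2, nxt)) break
    nxt <- nxt2
  }
  term_r <- ((nxt - 1L) %% nr) + 1L; term_c <- ((nxt - 1L) %/% nr) + 1L
  lab <- (pmin(floor((term_r - 1) / (nr / blocks)), blocks - 1) * blocks +
            pmin(floor((term_c - 1) / (nc / blocks)), blocks - 1)) + 1L
  grid_create(matrix(lab, nr, nc), direction$cell_size, direction$origin_x,
              direction$origin_y, kind = "categorical")
}

#' True suitability surface of a synthetic world
#'
#' Logistic in the true generating covariates: focal slope, focal TPI,
#' percent agriculture of the subwatershed, and March temperature.
#'
#' @param world an `rh_world`.
#' @param beta named coefficients (intercept, slope, tpi, pct_agriculture,
#'   temp).
#' @return a continuous `rh_grid` of probabilities.
#' @export
true_suitability <- function(world, beta = world$config$beta) {
  sl <- slope(world$dem, 120)$values
  tp <- tpi(world$dem, 120)$values
  ag <- watershed_pct(world$landcover, world$watersheds,
                      lc_groups()$agriculture)$values
  tm <- world$climate$temp_march$values
  eta <- beta[["intercept"]] + beta[["slope"]] * sl + beta[["tpi"]] * tp +
    beta[["pct_agriculture"]] * ag + beta[["temp"]] * tm
  grid_create(stats::plogis(eta), world$dem$cell_size, world$dem$origin_x,
              world$dem$origin_y)
}

#' Sample occurrence records from the suitability truth
#'
#' Presence cells are drawn without replacement, proportional to true
#' suitability, from the carved ravine cells; a road-proximity factor is
#' solved analytically so that the expected share of records within 100 m
#' of a road equals `road_bias`.  A `nymph_frac` share stays on the stream
#' cell; the rest are labeled adult and displaced up to 300 m to a
#' not-lower cell (emulating adults found upslope of the breeding seep).
#'
#' @param world an `rh_world`.
#' @param n number of records (default from the config).
#' @param nymph_frac,road_bias overrides of the config values.
#' @param seed RNG seed (default: substream of the world seed).
#' @return occurrence data.frame (x, y, year, life_stage, source).
#' @export
sample_occurrences <- function(world, n = world$config$n_occurrences,
                               nymph_frac = world$config$nymph_frac,
                               road_bias = world$config$road_bias,
                               seed = fan_seed(world$config$seed, 99)) {
  carved <- which(world$truth$carved$member)
  if (n > length(carved))
    stop("more occurrences requested than candidate stream cells")
  suit <- world$truth$suitability$values[carved]
  near <- world$roads_dist$values[carved] <= 100
  nr <- nrow(world$dem$values)
  dem <- world$dem$values
  cs <- world$dem$cell_size
  draw <- function(target_frac) with_seed(seed, {
    w <- suit
    if (target_frac > 0 && any(near) && any(!near)) {
      s_near <- sum(w[near]); s_far <- sum(w[!near])
      fac <- (target_frac / max(1 - target_frac, 1e-9)) *
        (s_far / max(s_near, 1e-12))
      w[near] <- w[near] * fac
    }
    pick <- sample(carved, n, prob = pmax(w, 1e-12))
    rows <- ((pick - 1L) %% nr) + 1L; cols <- ((pick - 1L) %/% nr) + 1L
    stage <- ifelse(seq_len(n) <= round(n * nymph_frac), "nymph", "adult")
    stage <- sample(stage)
    xy <- cell_center_xy(world$dem, rows, cols)
    # displace adults up to 300 m to a cell not lower than where they bred
    for (i in which(stage == "adult")) {
      off <- kernel_offsets(300, cs)
      cand <- cbind(rows[i] + off[, 1], cols[i] + off[, 2])
      ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 &
        cand[, 2] <= ncol(dem)
      cand <- cand[ok, , drop = FALSE]
      ok2 <- dem[cand] >= dem[rows[i], cols[i]] - 1e-9
      cand <- cand[ok2, , drop = FALSE]
      if (nrow(cand)) {
        j <- sample.int(nrow(cand), 1)
        xy[i, ] <- cell_center_xy(world$dem, cand[j, 1], cand[j, 2])
      }
    }
    year <- ifelse(stats::runif(n) < 0.85, sample(2013:2024, n, TRUE),
                   sample(2008:2012, n, TRUE))
    data.frame(x = xy[, 1], y = xy[, 2], year = year, life_stage = stage,
               source = sample(c("survey", "community"), n, TRUE,
                               prob = c(0.7, 0.3)),
               stringsAsFactors = FALSE)
  })
  # the adult displacement dilutes road proximity of the sampled cells, so
  # the cell-level target is calibrated by a short fixed-point iteration
  # until the realized record-level fraction matches road_bias
  target <- road_bias
  out <- draw(target)
  if (road_bias > 0) {
    for (it in 1:4) {
      rc <- cell_at(world$dem, out$x, out$y)
      got <- mean(world$roads_dist$values[rc] <= 100)
      if (abs(got - road_bias) < 0.03 || got <= 0) break
      target <- min(max(target * road_bias / got, 0.01), 0.95)
      out <- draw(target)
    }
  }
  out
}

#' Write the complete world bundle as plain-text files
#'
#' Grids and masks as ESRI ASCII rasters, occurrences as CSV, and the truth
#' bookkeeping as JSON, into `dir`.
#'
#' @param world an `rh_world`.
#' @param dir output directory.
#' @param occurrences optional occurrence data.frame to include.
#' @export
world_write <- function(world, dir, occurrences = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wg <- function(g, name) grid_write_asc(g, file.path(dir, paste0(name, ".asc")))
  wg(world$dem, "dem"); wg(world$landcover, "landcover")
  wg(world$canopy, "canopy")
  wg(world$soils$conductivity, "soil_conductivity")
  wg(world$soils$ph, "soil_ph"); wg(world$soils$pct_sand, "soil_pct_sand")
  wg(world$climate$temp_march, "temp_march")
  wg(world$climate$precip_march, "precip_march")
  wg(world$roads, "roads"); wg(world$protected, "protected")
  wg(world$plantations, "plantations"); wg(world$waterbodies, "waterbodies")
  wg(world$watersheds, "watersheds"); wg(world$regions, "regions")
  wg(world$sleuth, "sleuth"); wg(world$landform, "landform")
  wg(world$truth$suitability, "true_suitability")
  wg(world$truth$carved, "carved")
  if (!is.null(occurrences))
    occ_write_csv(occurrences, file.path(dir, "occurrences.csv"))
  jsonlite::write_json(list(config = world$config[setdiff(names(world$config),
                                                          "beta")],
                            beta = as.list(world$config$beta)),
                       file.path(dir, "world_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
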