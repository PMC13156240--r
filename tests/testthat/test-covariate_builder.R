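fake_stack <- function(layers, radius = 120) {
  structure(list(layers = layers, radius = radius, categorical = "landform"),
            class = "rh_stack")
}

test_that("build_stack assembles 12 layers with hand-checkable values", {
  n <- 24; cs <- 60
  lg <- lc_legend()
  dem <- grid_create(outer(seq_len(n), seq_len(n), function(i, j) j * 0.5), cs)
  lc <- matrix(lg[["evergreen_forest"]], n, n)
  lc[, 1:8] <- lg[["cultivated_crops"]]       # watershed 1 fully agricultural
  lc[, 17:24] <- lg[["developed_low"]]
  lcg <- grid_create(lc, cs, kind = "categorical")
  canopy <- grid_create(matrix(30, n, n), cs)
  ws <- grid_create(matrix(rep(rep(1:3, each = 8), n), n, n, byrow = TRUE),
                    cs, kind = "categorical")
  soils <- list(conductivity = flat_grid(n, 2, cs), ph = flat_grid(n, 6, cs),
                pct_sand = flat_grid(n, 80, cs))
  climate <- list(temp_march = flat_grid(n, 16, cs),
                  precip_march = flat_grid(n, 110, cs))
  seg <- local({
    cells <- cbind(2:20, 12)
    geo <- ravinehab:::seg_geometry(cells, cs)
    list(cells = cells, length_m = geo$length, sinuosity = geo$sinuosity,
         strahler = 1L, downstream = NA_integer_)
  })
  net <- structure(list(segments = list(seg), cell_size = cs, origin_x = 0,
                        origin_y = n * cs, dim = c(n, n)),
                   class = "rh_flownet")

  st <- build_stack(dem, lcg, canopy, soils, climate, net, ws, radius = 120)
  expect_setequal(names(st$layers), covariate_names())

  # fully agricultural watershed paints 100 on all its cells
  expect_true(all(st$layers$pct_agriculture$values[, 1:8] == 100))
  expect_true(all(st$layers$pct_agriculture$values[, 9:24] == 0))
  # middle watershed: evergreen, no development
  expect_true(all(st$layers$pct_developed$values[, 9:16] == 0))
  expect_true(all(st$layers$pct_developed$values[, 17:24] == 100))

  # qualifying terrestrial cell (evergreen, canopy < 50) has distance 0
  expect_equal(unname(st$layers$dist_terrestrial$values[12, 12]), 0)
  # agricultural cells are 1+ cells away from terrestrial classes
  expect_gt(st$layers$dist_terrestrial$values[12, 4], 0)
  # stream distance at a reach cell is 0
  expect_equal(unname(st$layers$dist_stream$values[10, 12]), 0)

  expect_error(build_stack(dem, lcg, canopy, soils["ph"], climate, net, ws),
               "conductivity")
})

test_that("collinearity screen: r, eta, thresholding, and the ANOVA oracle", {
  set.seed(21)
  n <- 300
  a <- rnorm(n)
  df <- data.frame(a = a, b = a * 2 + rnorm(n, sd = 1e-8),  # collinear pair
                   c = rnorm(n), landform = sample(1:5, n, TRUE))
  rep <- collinearity_screen(df, categorical = "landform", threshold = 0.7)
  ab <- rep[rep$var1 == "a" & rep$var2 == "b", ]
  expect_true(ab$flagged)
  expect_gt(ab$value, 0.999)
  ac <- rep[rep$var1 == "a" & rep$var2 == "c", ]
  expect_false(ac$flagged)
  expect_lt(ac$value, 0.2)

  # eta^2 equals the R^2 of a one-way ANOVA (independent oracle)
  g <- df$landform; v <- df$c
  eta <- correlation_ratio(g, v)
  r2 <- summary(stats::lm(v ~ factor(g)))$r.squared
  expect_equal(eta^2, r2, tolerance = 1e-12)

  # a categorical that perfectly partitions a continuous layer: eta = 1
  vv <- c(rep(1, 50), rep(10, 50))
  gg <- c(rep(1, 50), rep(2, 50))
  expect_equal(correlation_ratio(gg, vv), 1)

  # zero-variance layer excluded with warning
  df$z <- 1
  expect_warning(collinearity_screen(df, categorical = "landform"), "z")
})

test_that("woe_iv behaves at the boundary cases", {
  set.seed(2)
  x <- rnorm(2000)
  same <- woe_iv(sample(x, 300), x)
  expect_lt(abs(same$iv), 0.15)          # identical distributions: IV ~ 0
  expect_gte(same$iv, 0)                  # IV is never negative

  # presences all in the top decile: IV > 1
  bg <- runif(2000)
  pres <- runif(200, 0.95, 1)
  expect_gt(woe_iv(pres, bg)$iv, 1)
})

test_that("IV is nonnegative over random presence/background draws", {
  set.seed(14)
  for (rep in 1:10) {
    bg <- rnorm(500)
    pres <- rnorm(80, mean = runif(1, -1, 1))
    expect_gte(woe_iv(pres, bg)$iv, -1e-12)
  }
})

test_that("select_radius prefers the generating radius", {
  set.seed(77)
  n <- 60; cs <- 60
  noise <- grid_create(matrix(rnorm(n * n), n, n), cs)
  s120 <- focal_stat(noise, 120, "mean")
  s540 <- focal_stat(noise, 540, "mean")
  other <- function() grid_create(matrix(rnorm(n * n), n, n), cs)
  mk <- function(slope_layer) fake_stack(list(
    slope = slope_layer, tpi = other(), conductivity = other(),
    ph = other(), pct_sand = other()))
  stacks <- list("120" = mk(s120), "540" = mk(s540))
  # presences in the top decile of the 120-m layer
  q <- stats::quantile(s120$values, 0.9)
  pres <- which(s120$values >= q, arr.ind = TRUE)
  pres <- pres[sample(nrow(pres), 60), ]
  bg <- cbind(sample(n, 400, TRUE), sample(n, 400, TRUE))
  sel <- select_radius(stacks, pres, bg)
  expect_equal(sel$radius, 120)
  expect_error(select_radius(stacks["120"], pres, bg), "at least 2")
  expect_error(select_radius(stacks, pres[0, , drop = FALSE], bg),
               "no presences")
})

test_that("area change arithmetic reproduces the published table", {
  areas <- utils::read.csv(system.file("extdata",
                                       "landcover_class_areas.csv",
                                       package = "ravinehab"))
  a08 <- stats::setNames(areas$area_2008_km2, areas$class)
  a19 <- stats::setNames(areas$area_2019_km2, areas$class)
  a24 <- stats::setNames(areas$area_2024_km2, areas$class)
  ch <- area_change_table(a08, a24)
  ev <- ch[ch$class == "evergreen_forest", ]
  expect_equal(ev$delta_km2, -2979)
  expect_equal(round(ev$delta_relpct, 1), -2.5)
  hb <- ch[ch$class == "herbaceous", ]
  expect_equal(round(hb$delta_relpct, 1), 1.3)
  expect_equal(ch[ch$class == "shrub_scrub", "delta_km2"], 1187)
  ch2 <- area_change_table(a19, a24)
  expect_equal(ch2[ch2$class == "cultivated_crops", "delta_km2"], -541)
  # relative changes sum to zero by construction
  expect_lt(abs(sum(ch$delta_relpct)), 1e-9)

  # two-class toy: A goes 25% -> 50% of a constant total
  toy <- area_change_table(c(A = 25, B = 75), c(A = 50, B = 50))
  expect_equal(toy[toy$class == "A", "delta_relpct"], 25)

  expect_error(area_change_table(c(A = 1), c(B = 1)), "legend")
})

test_that("landcover_change tabulates grids and matches identical-grid zeroes", {
  lg <- lc_legend()
  v <- matrix(lg[["evergreen_forest"]], 10, 10)
  v[1:5, 1:4] <- lg[["herbaceous"]]
  g1 <- grid_create(v, 60, kind = "categorical")
  v2 <- v; v2[1:2, 1:4] <- lg[["shrub_scrub"]]
  g2 <- grid_create(v2, 60, kind = "categorical")
  ch <- landcover_change(g1, g2)
  cell <- 0.0036
  expect_equal(ch[ch$class == "52", "delta_km2"], 8 * cell)
  expect_equal(ch[ch$class == "71", "delta_km2"], -8 * cell)
  same <- landcover_change(g1, g1)
  expect_true(all(same$delta_km2 == 0))
  expect_true(all(same$delta_relpct == 0))
})

test_that("occurrence change flags mark multi-class sequences", {
  lg <- lc_legend()
  mk <- function(code) grid_create(matrix(code, 6, 6), 60,
                                   kind = "categorical")
  epochs <- list(e1 = mk(lg[["evergreen_forest"]]),
                 e2 = mk(lg[["herbaceous"]]),
                 e3 = mk(lg[["shrub_scrub"]]))
  same <- list(e1 = mk(42), e2 = mk(42), e3 = mk(42))
  r <- data.frame(x = c(90, 150, 210), y = c(90, 150, 210), year = 2020,
                  life_stage = "nymph", source = "s")
  fl <- occurrence_change_flags(r, epochs)
  expect_true(all(fl$changed))
  fl2 <- occurrence_change_flags(r, same)
  expect_false(any(fl2$changed))
  expect_error(occurrence_change_flags(r, epochs[1]), "2 epochs")
})
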