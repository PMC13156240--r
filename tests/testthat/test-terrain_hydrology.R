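test_that("slope is exact on planes and shift-invariant", {
  flat <- flat_grid(10, value = 100)
  expect_true(all(abs(slope(flat, 120)$values) < 1e-12))

  # plane rising 1 m per 60-m cell -> atan(1/60) ~ 0.955 degrees (interior)
  pl <- plane_grid(10, 10, per_cell = 1, cs = 60)
  s <- slope(pl, radius = NULL)
  expect_equal(unname(s$values[5, 5]), atan(1 / 60) * 180 / pi,
               tolerance = 1e-10)

  pl2 <- pl; pl2$values <- pl2$values + 500
  expect_equal(slope(pl2, 120)$values, slope(pl, 120)$values)
})

test_that("tpi matches the focal-mean arithmetic and is shift-invariant", {
  flat <- flat_grid(9, value = 42)
  expect_true(all(abs(tpi(flat, 120)$values) < 1e-12))

  # lone peak +h on a flat plain: neighborhood of n cells -> h (n-1)/n
  v <- matrix(0, 9, 9); v[5, 5] <- 12
  g <- grid_create(v, 60)
  t1 <- tpi(g, 60)                       # 5-cell plus neighborhood
  expect_equal(unname(t1$values[5, 5]), 12 * (5 - 1) / 5)

  g2 <- g; g2$values <- g2$values + 7
  expect_equal(tpi(g2, 120)$values, tpi(g, 120)$values)
})

test_that("geomorphons classify flat, peak, and valley archetypes", {
  flat <- flat_grid(25, value = 10)
  gm <- geomorphons(flat, search_cells = 5, skip_cells = 1, flat_deg = 1)
  expect_true(all(gm$values[8:18, 8:18] == 1))   # Flat

  # strict conical local maximum -> Peak (all-minus pattern)
  n <- 25; ctr <- 13
  cone <- grid_create(500 - outer(seq_len(n), seq_len(n), function(i, j)
    sqrt((i - ctr)^2 + (j - ctr)^2)) * 30, 60)
  gmc <- geomorphons(cone, search_cells = 5, skip_cells = 1, flat_deg = 1)
  expect_equal(unname(gmc$values[ctr, ctr]), 2)

  # V-valley floor -> Valley (terrain above in 6 of 8 directions)
  vv <- v_valley_dem(21, vcol = 11, slope = 5)
  gmv <- geomorphons(vv, search_cells = 5, skip_cells = 1, flat_deg = 1)
  expect_equal(unname(gmv$values[11, 11]), 9)
  # valley walls are slopes
  expect_equal(unname(gmv$values[11, 6]), 6)
})

test_that("d8 accumulation matches toy funnels and the path-count oracle", {
  # 5x5 funnel: everything drains to the center-bottom outlet
  z <- outer(1:5, 1:5, function(i, j) (abs(j - 3) + (5 - i)) * 2)
  funnel <- grid_create(z, 60)
  fl <- d8_flow(funnel)
  expect_equal(max(fl$accumulation$values, na.rm = TRUE), 24)
  expect_equal(unname(fl$accumulation$values[5, 3]), 24)

  # inclined plane: accumulation increases monotonically downslope
  pl <- plane_grid(6, 6, per_cell = 1)
  ac <- d8_flow(pl)$accumulation$values
  for (i in 1:6) expect_true(all(diff(rev(ac[i, ])) >= 0))

  # oracle: accumulation at a cell = number of cells whose D8 path passes
  # through it (computed by independently tracing every path)
  set.seed(11)
  for (rep in 1:3) {
    z <- matrix(cumsum(rnorm(100, 0.2)), 10, 10) +
      outer(1:10, 1:10, function(i, j) j * 0.5)
    dem <- grid_create(z, 60)
    fl <- d8_flow(dem)
    dir <- fl$direction$values
    cnt <- matrix(0, 10, 10)
    for (r in 1:10) for (cc in 1:10) {
      pr <- r; pc <- cc
      for (step in 1:1000) {
        dd <- dir[pr, pc]
        if (dd == 0) break
        pr2 <- pr + c(-1, -1, 0, 1, 1, 1, 0, -1)[dd]
        pc2 <- pc + c(0, 1, 1, 1, 0, -1, -1, -1)[dd]
        if (pr2 < 1 || pr2 > 10 || pc2 < 1 || pc2 > 10) break
        cnt[pr2, pc2] <- cnt[pr2, pc2] + 1
        pr <- pr2; pc <- pc2
      }
    }
    expect_equal(fl$accumulation$values, cnt)
  }
})

test_that("depression filling drains every interior cell", {
  set.seed(5)
  z <- matrix(runif(144, 0, 10), 12, 12)
  z[5:7, 5:7] <- -20                        # a deep pit
  filled <- fill_depressions(grid_create(z, 60))$values
  # every interior cell has a strictly lower 8-neighbor
  for (r in 2:11) for (cc in 2:11) {
    nb <- filled[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    expect_true(min(nb[-5]) < filled[r, cc])
  }
})

test_that("strahler ordering equals the recursive oracle on random trees", {
  strahler_oracle <- function(down) {
    rec <- function(s) {
      ups <- which(down == s)
      if (length(ups) == 0) return(1L)
      o <- vapply(ups, rec, 0L)
      m <- max(o)
      if (sum(o == m) >= 2) m + 1L else m
    }
    vapply(seq_along(down), rec, 0L)
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    # random forest: each node drains to a strictly later node (or outlet)
    down <- vapply(seq_len(n), function(i) {
      if (i == n || stats::runif(1) < 0.15) return(NA_integer_)
      cand <- (i + 1):n
      as.integer(cand[sample.int(length(cand), 1)])
    }, NA_integer_)
    expect_identical(ravinehab:::strahler_from_links(down),
                     strahler_oracle(down))
  }
})

test_that("extract_flowlines splits a Y-network into ordered segments", {
  # hand-specified direction/accumulation Y: two tributaries at columns 3/5
  # merging diagonally into a trunk down column 4 (codes: 1 N, 2 NE, 3 E,
  # 4 SE, 5 S, 6 SW, 7 W, 8 NW)
  n <- 9
  dir <- matrix(5L, n, n); acc <- matrix(0, n, n)
  left <- rbind(c(1, 3), c(2, 3), c(3, 3))
  right <- rbind(c(1, 5), c(2, 5), c(3, 5))
  trunk <- cbind(4:9, 4)
  acc[left] <- 10; acc[right] <- 10; acc[trunk] <- 30
  dir[left] <- 5L; dir[3, 3] <- 4L            # SE into the junction
  dir[right] <- 5L; dir[3, 5] <- 6L           # SW into the junction
  dir[trunk] <- 5L
  accg <- grid_create(acc, 60)
  dirg <- grid_create(dir, 60, kind = "categorical")
  net <- extract_flowlines(accg, dirg, threshold = 5, keep_orders = 1:3)
  ords <- vapply(net$segments, `[[`, 0L, "strahler")
  expect_length(net$segments, 3)
  expect_equal(sort(ords), c(1L, 1L, 2L))
  # the two order-1 tributaries drain into the order-2 trunk
  o1 <- which(ords == 1)
  dstr <- vapply(net$segments[o1], `[[`, 0L, "downstream")
  expect_true(all(ords[dstr] == 2))
  # an order-1 joining an order-2 keeps order 2 downstream: add a side
  # tributary into the trunk interior
  acc2 <- acc; dir2 <- dir
  side <- rbind(c(6, 2), c(7, 3))
  acc2[side] <- 10; dir2[6, 2] <- 5L; dir2[7, 3] <- 4L  # SE into (8,4)
  net2 <- extract_flowlines(grid_create(acc2, 60),
                            grid_create(dir2, 60, kind = "categorical"),
                            threshold = 5, keep_orders = 1:3)
  ords2 <- vapply(net2$segments, `[[`, 0L, "strahler")
  expect_equal(max(ords2), 2L)
  expect_equal(sum(ords2 == 2), 2)  # trunk split at the side junction

  # sinuosity of a straight segment is 1; lengths are polyline lengths
  trunk_seg <- net$segments[[which(ords == 2)]]
  expect_equal(trunk_seg$sinuosity, 1)
  expect_equal(trunk_seg$length_m, (nrow(trunk_seg$cells) - 1) * 60)

  # empty network below threshold
  net0 <- extract_flowlines(accg, dirg, threshold = 1e6)
  expect_length(net0$segments, 0)

  # DEM-driven smoke check: a funnel yields a connected low-order network
  z <- outer(1:12, 1:12, function(i, j) (abs(j - 6) + (12 - i)) * 2)
  fl <- d8_flow(grid_create(z, 60))
  netf <- extract_flowlines(fl$accumulation, fl$direction, threshold = 8)
  expect_gte(length(netf$segments), 1)
})

# hand-built six-segment network exercising every cleaning rule
toy_net_for_cleaning <- function() {
  nr <- 40; nc <- 40; cs <- 60
  seg <- function(cells) {
    geo <- ravinehab:::seg_geometry(cells, cs)
    list(cells = cells, length_m = geo$length, sinuosity = geo$sinuosity,
         strahler = 1L, downstream = NA_integer_)
  }
  wiggle <- function(r0, c0, len) {
    rows <- r0 + cumsum(c(0, rep(c(1, 0), length.out = len - 1)))
    cols <- c0 + seq_len(len) - 1
    cbind(rows, cols)
  }
  segments <- list(
    seg(wiggle(5, 5, 8)),                       # 1 good
    seg(cbind(20, 5:16)),                       # 2 straight 660 m artifact
    seg(wiggle(5, 20, 8)),                      # 3 inside lake
    seg(wiggle(25, 20, 8)),                     # 4 off ravine landform
    seg(cbind(35, 35:36)),                      # 5 short + isolated (60 m)
    seg(wiggle(8, 7, 6)))                       # 6 good, near segment 1
  net <- structure(list(segments = segments, cell_size = cs,
                        origin_x = 0, origin_y = nr * cs, dim = c(nr, nc)),
                   class = "rh_flownet")
  lake <- matrix(FALSE, nr, nc); lake[1:16, 18:30] <- TRUE
  landform <- matrix(9, nr, nc); landform[20:30, 15:30] <- 3
  ww <- matrix(TRUE, nr, nc)
  ref_cells <- cbind(1:30, 3)
  ref <- structure(list(segments = list(seg(ref_cells)), cell_size = cs,
                        origin_x = 0, origin_y = nr * cs, dim = c(nr, nc)),
                   class = "rh_flownet")
  list(net = net, lake = mask_create(lake, cell_size = cs),
       landform = grid_create(landform, cs, kind = "categorical"),
       ww = mask_create(ww, cell_size = cs), ref = ref)
}

test_that("clean_flowlines applies the five rules and is idempotent", {
  fx <- toy_net_for_cleaning()
  cleaned <- clean_flowlines(fx$net, fx$lake, fx$ref, fx$landform, fx$ww)
  rules <- attr(cleaned, "removal_rule")
  expect_equal(rules, c(0L, 2L, 1L, 4L, 5L, 0L))
  expect_length(cleaned$segments, 2)

  # pure filter + idempotence
  again <- clean_flowlines(cleaned, fx$lake, fx$ref, fx$landform, fx$ww)
  expect_equal(length(again$segments), length(cleaned$segments))
  expect_equal(attr(again, "removal_rule"), c(0L, 0L))

  # empty reference network: rule 3 skipped with a warning
  empty_ref <- fx$ref; empty_ref$segments <- list()
  expect_warning(clean_flowlines(fx$net, fx$lake, empty_ref, fx$landform,
                                 fx$ww), "rule 3")

  # reference-distance helper exposes mean + 2 SD
  st <- reference_distance_stats(fx$net, fx$ref)
  expect_length(st$dist, 6)
  expect_equal(st$cutoff, st$mean + 2 * st$sd)
})

test_that("flownet CSV export writes one row per segment", {
  fx <- toy_net_for_cleaning()
  p <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  flownet_write_csv(fx$net, p, cells_json = pj)
  df <- utils::read.csv(p)
  expect_equal(nrow(df), 6)
  expect_true(all(c("strahler_order", "length_m", "sinuosity") %in% names(df)))
  expect_length(jsonlite::read_json(pj), 6)
})
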