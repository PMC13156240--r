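# helper: build an rh_maxent by hand from a feature set, coefficients, and
# background rows (normalizer and entropy computed from the definition)
manual_model <- function(fs, lambda, bg_data) {
  Xb <- feature_matrix(fs, bg_data)
  eta <- as.vector(Xb %*% lambda)
  logZ <- ravinehab:::log_sum_exp(eta)
  raw <- exp(eta - logZ)
  H <- -sum(raw * log(pmax(raw, 1e-300)))
  structure(list(features = fs, lambda = stats::setNames(lambda, colnames(Xb)),
                 rm = 1, logZ = logZ, entropy = H, bg_data = bg_data,
                 objective_trace = NULL, converged = TRUE),
            class = "rh_maxent")
}

test_that("sample_background restricts to valley landforms with road bias", {
  n <- 80
  lf <- matrix(3, n, n)
  lf[, 1:40] <- 9                      # eligible half: 3200 cells
  lfg <- grid_create(lf, 60, kind = "categorical")
  rd <- matrix(600, n, n); rd[1:40, ] <- 0   # near-road upper half
  rdg <- grid_create(rd, 60)

  # tau = Inf: uniform over classes 6-10 (chi-square over 8 equal bins)
  bgu <- sample_background(800, lfg, rdg, tau = Inf, seed = 2)
  expect_true(all(lf[bgu$cells] == 9))
  bins <- cut(bgu$cells[, 1] + (bgu$cells[, 2] - 1) * n, breaks = 8)
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)

  # tau = 200 with d = 0 vs 600: near cells weighted e^3 ~ 20x
  bgb <- sample_background(400, lfg, rdg, tau = 200, seed = 3)
  near <- sum(bgb$cells[, 1] <= 40); far <- 400 - near
  rate_ratio <- (near / 1600) / max(far / 1600, 1 / 1600)
  expect_gt(near / 400, 0.9)
  expect_gt(rate_ratio, 8)

  # fewer eligible cells than requested: all returned with a warning
  small <- grid_create(matrix(c(9, rep(1, 24)), 5, 5), 60,
                       kind = "categorical")
  smd <- grid_create(matrix(0, 5, 5), 60)
  expect_warning(bs <- sample_background(10, small, smd, seed = 1),
                 "eligible")
  expect_equal(nrow(bs$cells), 1)
  expect_error(sample_background(10, grid_create(matrix(1, 3, 3), 60,
                                                 kind = "categorical"),
                                 smd), "eligible")
})

test_that("feature expansion: hinges, combinatorics, scaling, categoricals", {
  df <- data.frame(a = c(0, 2.5, 5, 7.5, 10), b = c(1, 2, 3, 4, 5))
  fs <- make_features(df, 3, classes = c("L", "Q", "P"), categorical = NULL)
  expect_length(fs$defs, 5)            # 2 L + 2 Q + 1 P

  # forward hinge at knot 5 on range [0,10]: 3 -> 0, 7.5 -> 0.5
  fsh <- structure(list(defs = list(
    list(type = "hinge_fwd", var = "a", knot = 5, scale = c(0, 10),
         beta = 0.5, name = "h")), continuous = "a",
    ranges = list(a = c(0, 10)), categorical = NULL, n_presence = 3),
    class = "rh_features")
  hv <- feature_matrix(fsh, data.frame(a = c(3, 7.5, 10)))
  expect_equal(unname(hv[, 1]), c(0, 0.5, 1))

  # all features land in [0,1] on the training sample
  set.seed(4)
  big <- data.frame(a = rnorm(100), b = runif(100), landform = sample(6:10, 100, TRUE))
  fsb <- make_features(big, 20, n_hinge = 5)
  M <- feature_matrix(fsb, big)
  expect_true(all(M >= 0 & M <= 1))
  # one indicator per observed landform class
  expect_equal(sum(vapply(fsb$defs, `[[`, "", "type") == "indicator"), 5)

  # constant variables are dropped
  cst <- data.frame(a = rnorm(50), z = 1)
  fsc <- make_features(cst, 10, classes = "L", categorical = NULL)
  expect_equal(vapply(fsc$defs, `[[`, "", "var"), "a")

  # betas follow the class defaults
  types <- vapply(fsb$defs, `[[`, "", "type")
  betas <- vapply(fsb$defs, `[[`, 0, "beta")
  expect_true(all(betas[types == "linear"] == 1 / sqrt(20)))
  expect_true(all(betas[grepl("hinge", types)] == 0.5))
  expect_true(all(betas[types == "indicator"] == 0.25))
})

test_that("fit_maxent: uniform at zero, gradient sign, monotone objective", {
  set.seed(9)
  bg <- data.frame(v = runif(400))
  pres <- data.frame(v = runif(30, 0.7, 1))   # concentrated at high values
  fs <- make_features(rbind(pres, bg), nrow(pres), classes = "L",
                      categorical = NULL)

  # enormous penalty keeps lambda at zero: raw = 1/N over background
  m0 <- fit_maxent(fs, pres, bg, rm = 1e6)
  expect_true(all(m0$lambda == 0))
  expect_equal(unname(predict(m0, bg, output = "raw")),
               rep(1 / nrow(bg), nrow(bg)))

  m <- fit_maxent(fs, pres, bg, rm = 1)
  expect_gt(m$lambda[["v"]], 0)
  expect_true(m$converged)
  expect_true(all(diff(m$objective_trace) <= 1e-10))

  # rm -> infinity drives all coefficients to zero
  expect_true(all(fit_maxent(fs, pres, bg, rm = 100)$lambda == 0))
})

test_that("fitted coefficients match a shrinking-grid-search oracle", {
  set.seed(12)
  bg <- data.frame(a = runif(20), b = runif(20))
  pres <- data.frame(a = runif(8, 0.5, 1), b = runif(8, 0, 0.6))
  fs <- make_features(rbind(pres, bg), nrow(pres), classes = "L",
                      categorical = NULL)
  m <- fit_maxent(fs, pres, bg, rm = 1, tol = 1e-9)

  # independent oracle: direct minimization of the same objective by
  # iteratively refined grid search over the two coefficients
  Xp <- feature_matrix(fs, pres); Xb <- feature_matrix(fs, bg)
  pen <- vapply(fs$defs, `[[`, 0, "beta")
  obj <- function(l) {
    eta <- Xb %*% l
    -mean(Xp %*% l) + log(sum(exp(eta))) + sum(pen * abs(l))
  }
  lo <- c(-6, -6); hi <- c(6, 6)
  for (it in 1:40) {
    g1 <- seq(lo[1], hi[1], length.out = 15)
    g2 <- seq(lo[2], hi[2], length.out = 15)
    vals <- outer(g1, g2, Vectorize(function(x, y) obj(c(x, y))))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    ctr <- c(g1[ix[1]], g2[ix[2]])
    span <- (hi - lo) * 0.35
    lo <- ctr - span / 2; hi <- ctr + span / 2
  }
  expect_equal(unname(m$lambda), ctr, tolerance = 1e-3)
  expect_lte(obj(m$lambda), obj(ctr) + 1e-8)
})

test_that("prediction: cloglog transform, monotonicity, normalization", {
  set.seed(3)
  bg <- data.frame(v = runif(200))
  pres <- data.frame(v = runif(20, 0.5, 1))
  fs <- make_features(rbind(pres, bg), 20, classes = c("L", "Q"),
                      categorical = NULL)
  m <- fit_maxent(fs, pres, bg)
  raw <- predict(m, bg, output = "raw")
  expect_equal(sum(raw), 1)
  cl <- predict(m, bg, output = "cloglog")
  expect_true(all(cl > 0 & cl < 1))
  expect_equal(order(raw), order(cl))   # strictly increasing transform

  # uniform raw over N cells: H = ln N, cloglog = 1 - exp(-1)
  m0 <- fit_maxent(fs, pres, bg, rm = 1e6)
  expect_equal(m0$entropy, log(nrow(bg)))
  expect_equal(unname(predict(m0, bg)), rep(1 - exp(-1), nrow(bg)))

  # out-of-range covariates are clamped with a warning
  expect_warning(predict(m, data.frame(v = 99)), "clamped")

  # JSON round trip preserves predictions
  p <- withr::local_tempfile(fileext = ".json")
  maxent_write_json(m, p)
  m2 <- maxent_read_json(p)
  # last-bit float loss in JSON can nudge a boundary value past the range
  expect_equal(suppressWarnings(predict(m2, bg)), predict(m, bg),
               tolerance = 1e-12)
})

test_that("aicc arithmetic and edge cases", {
  set.seed(6)
  bg <- data.frame(v = runif(150))
  pres <- data.frame(v = runif(12, 0.6, 1))
  fs <- make_features(rbind(pres, bg), 12, classes = "L", categorical = NULL)
  m <- fit_maxent(fs, pres, bg)
  a <- aicc(m, pres)
  expect_equal(a$k, sum(m$lambda != 0))
  expect_equal(a$aicc,
               2 * a$k - 2 * a$logL + 2 * a$k * (a$k + 1) / (a$n - a$k - 1))

  # k = 3, n = 132, logL = -500 -> 1006.1875 (formula plug-in)
  expect_equal(2 * 3 - 2 * (-500) + 2 * 3 * 4 / (132 - 3 - 1), 1006.1875)

  # n <= k + 1 -> undefined
  tiny <- pres[1:2, , drop = FALSE]
  mt <- fit_maxent(fs, tiny, bg)
  at <- aicc(mt, tiny)
  if (at$k >= 1) expect_true(is.na(at$aicc))
})

test_that("select_model picks the lowest AICc and honors tie-breaks", {
  set.seed(31)
  bg <- data.frame(v = runif(300), w = runif(300))
  # presences generated with pure quadratic (U-shaped) structure in v:
  # invisible to a linear-only model, detectable by LQ
  cand <- data.frame(v = runif(5000), w = runif(5000))
  pv <- (2 * abs(cand$v - 0.5))^3
  pres <- cand[sample(nrow(cand), 200, prob = pv), ]

  single <- select_model(pres, bg, rm_grid = 1, class_grid = list("L"),
                         categorical = NULL)
  expect_equal(nrow(single$records), 1)
  expect_s3_class(single$model, "rh_maxent")

  sel <- select_model(pres, bg, rm_grid = 1,
                      class_grid = list("L", c("L", "Q")),
                      categorical = NULL)
  expect_equal(sel$records$classes[sel$best], "LQ")
})

test_that("crossvalidate partitions presences and averages maps", {
  set.seed(13)
  bg <- data.frame(v = runif(100))
  pres <- data.frame(v = runif(10, 0.5, 1))
  cv <- crossvalidate(pres, bg, k = 2, seed = 5, classes = "L",
                      categorical = NULL)
  expect_equal(as.vector(table(cv$fold)), c(5, 5))
  expect_true(all(!is.na(cv$pos_scores)))   # every presence scored once
  expect_length(cv$models, 2)
  expect_error(crossvalidate(pres, bg, k = 11), "exceeds")

  # mean map equals the arithmetic mean of the fold maps on a tiny stack
  st <- structure(list(layers = list(
    v = grid_create(matrix(c(0.1, 0.5, 0.9), 1, 3), 60)),
    radius = 120, categorical = character(0)), class = "rh_stack")
  cv2 <- crossvalidate(pres, bg, k = 2, seed = 5, classes = "L",
                       categorical = NULL, stack = st)
  manual <- (predict_map(cv2$models[[1]], st)$values +
               predict_map(cv2$models[[2]], st)$values) / 2
  expect_equal(cv2$mean_map$values, manual)
})
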