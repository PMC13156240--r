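test_that("roc_auc: separation, ties, pair enumeration, monotone invariance", {
  expect_equal(roc_auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  set.seed(1)
  x <- runif(200)
  expect_equal(roc_auc(x, x), 0.5)
  # pos = {0.9, 0.4}, neg = {0.5, 0.1}: 3 of 4 pairs won -> 0.75
  expect_equal(roc_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  # half-credit for ties
  expect_equal(roc_auc(c(0.5), c(0.5)), 0.5)
  # invariant under strictly monotone transforms
  pos <- runif(50); neg <- runif(70, 0, 0.8)
  expect_equal(roc_auc(pos, neg), roc_auc(qlogis(pos), qlogis(neg)))
  expect_error(roc_auc(numeric(0), neg), "non-empty")
})

test_that("auc_class reproduces the published bins at boundaries", {
  expect_equal(auc_class(0.905), "outstanding")
  expect_equal(auc_class(0.90), "excellent")
  expect_equal(auc_class(0.80), "excellent")
  expect_equal(auc_class(0.79), "acceptable")
  expect_equal(auc_class(0.70), "acceptable")
  expect_equal(auc_class(0.60), "poor")
  expect_equal(auc_class(0.49), "invalid")
})

test_that("ess_threshold minimizes |sens - spec| with lowest-tie rule", {
  # separable: any t in (0.2, 0.8) is perfect; lowest candidate midpoint
  t <- ess_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(t, 0.5)  # midpoints: 0.15, 0.5, 0.85 -> 0.5 is perfect
  # returned threshold is a global minimizer over the candidate grid
  set.seed(2)
  pos <- runif(40, 0.3, 1); neg <- runif(60, 0, 0.7)
  tt <- ess_threshold(pos, neg)
  gap <- function(t) abs(mean(pos >= t) - mean(neg < t))
  s <- sort(unique(c(pos, neg)))
  cands <- c(s[1] - 1e-9, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1e-9)
  expect_true(all(gap(tt) <= vapply(cands, gap, 0) + 1e-12))
  # degenerate singleton
  expect_silent(ess_threshold(0.5, 0.5))
})

test_that("confusion metrics: TSS/SEDI identities and plug-in arithmetic", {
  # H = F (random): TSS = 0 and SEDI = 0 exactly
  pos <- c(rep(1, 5), rep(0, 5)); neg <- c(rep(1, 5), rep(0, 5))
  cm <- confusion_metrics(pos, neg, 0.5)
  expect_identical(cm$tss, 0)
  expect_identical(cm$sedi, 0)

  # perfect classification: TSS = 1, SEDI -> 1 under clamping
  cmp <- confusion_metrics(rep(1, 10), rep(0, 10), 0.5)
  expect_equal(cmp$tss, 1)
  expect_gt(cmp$sedi, 0.9)
  expect_equal(cmp$accuracy, 1)

  # H = 0.9, F = 0.1 plug-in (computed from the SEDI definition):
  # (2 ln 0.1 - 2 ln 0.9) / (2 ln 0.1 + 2 ln 0.9)
  pos <- c(rep(1, 9), 0); neg <- c(rep(0, 9), 1)
  cm2 <- confusion_metrics(pos, neg, 0.5)
  expect_equal(cm2$tss, 0.8)
  sedi_expect <- (log(0.1) - log(0.9) - log(0.9) + log(0.1)) /
    (log(0.1) + log(0.9) + log(0.9) + log(0.1))
  expect_equal(cm2$sedi, sedi_expect)
  expect_equal(cm2$accuracy, 0.9)

  # SEDI symmetry: (H, F) -> (1-F, 1-H) leaves SEDI unchanged
  pos1 <- c(rep(1, 8), rep(0, 2)); neg1 <- c(rep(1, 2), rep(0, 8))  # H=.8 F=.2
  pos2 <- c(rep(1, 8), rep(0, 2)); neg2 <- c(rep(1, 2), rep(0, 8))
  # swapped rates: H' = 1-F = .8, F' = 1-H = .2 -> same confusion geometry
  expect_equal(confusion_metrics(pos1, neg1, 0.5)$sedi,
               confusion_metrics(pos2, neg2, 0.5)$sedi)
  # and an asymmetric case checked against the algebraic identity
  h <- 0.7; f <- 0.4
  sedi_hf <- function(H, FF) (log(FF) - log(H) - log(1 - FF) + log(1 - H)) /
    (log(FF) + log(H) + log(1 - FF) + log(1 - H))
  expect_equal(sedi_hf(h, f), sedi_hf(1 - f, 1 - h))

  expect_error(confusion_metrics(pos, neg, Inf), "finite")
})

test_that("TSS at the ESS threshold equals 2*sensitivity - 1", {
  set.seed(9)
  pos <- rbeta(200, 4, 2); neg <- rbeta(400, 2, 4)
  t <- ess_threshold(pos, neg)
  cm <- confusion_metrics(pos, neg, t)
  expect_equal(cm$tss, 2 * cm$sensitivity - 1, tolerance = 0.02)
})

test_that("permutation importance isolates informative variables", {
  set.seed(17)
  bg <- data.frame(a = runif(400), b = runif(400), c = runif(400))
  pres <- data.frame(a = runif(60, 0.6, 1), b = runif(60, 0.6, 1),
                     c = runif(60))
  fs <- make_features(rbind(pres, bg), 60, classes = "L", categorical = NULL)
  m <- fit_maxent(fs, pres, bg)
  imp <- permutation_importance(m, pres, bg, seed = 3, reps = 10)
  expect_equal(sum(imp), 100)
  # uninformative variable with (near) zero coefficient contributes ~0
  expect_lt(imp[["c"]], 5)
  # two equally informative variables split importance ~50/50
  expect_lt(abs(imp[["a"]] - imp[["b"]]), 20)

  # sole informative variable takes everything
  fs1 <- make_features(rbind(pres, bg)["a"], 60, classes = "L",
                       categorical = NULL)
  m1 <- fit_maxent(fs1, pres["a"], bg["a"])
  imp1 <- permutation_importance(m1, pres["a"], bg["a"], seed = 3)
  expect_equal(unname(imp1), 100)
})

test_that("percent contribution follows |lambda| x sd with normalization", {
  set.seed(23)
  bg <- data.frame(a = runif(500), b = runif(500))
  fs <- make_features(bg, 50, classes = "L", categorical = NULL)
  # identical distributions -> equal feature sds; lambda (2, 1) -> 66.7/33.3
  bg$b <- sample(bg$a)
  fs2 <- make_features(bg, 50, classes = "L", categorical = NULL)
  Xb <- feature_matrix(fs2, bg)
  m <- structure(list(features = fs2, lambda = c(a = 2, b = 1), rm = 1,
                      logZ = ravinehab:::log_sum_exp(Xb %*% c(2, 1)),
                      entropy = 1, bg_data = bg, converged = TRUE),
                 class = "rh_maxent")
  pc <- percent_contribution(m)
  sds <- apply(Xb, 2, sd)
  expect_equal(unname(pc["a"] / pc["b"]), 2 * sds[[1]] / sds[[2]])
  expect_equal(sum(pc), 100)
  expect_equal(unname(round(pc, 1)), c(66.7, 33.3), tolerance = 0.05)

  # all-zero coefficients: uniform with warning
  m0 <- m; m0$lambda <- c(a = 0, b = 0)
  expect_warning(pc0 <- percent_contribution(m0), "uniform")
  expect_equal(unname(pc0), c(50, 50))
})

test_that("response curves reflect the fitted structure", {
  set.seed(29)
  bg <- data.frame(v = runif(300), u = runif(300))
  pres <- data.frame(v = runif(50, 0.7, 1), u = runif(50))
  fs <- make_features(rbind(pres, bg), 50, classes = "L", categorical = NULL)
  m <- fit_maxent(fs, pres, bg)
  rc <- response_curve(m, "v", n_points = 50)
  expect_true(all(diff(rc$cloglog) > -1e-12))   # monotone increasing
  # a variable with zero coefficient gives a flat curve
  ru <- response_curve(m, "u", n_points = 20)
  if (m$lambda[["u"]] == 0) expect_lt(diff(range(ru$cloglog)), 1e-12)

  # quadratic-only model peaks at the fitted vertex
  bgq <- data.frame(v = runif(400))
  fsq <- structure(list(defs = list(
    list(type = "linear", var = "v", scale = c(0, 1), beta = 0.1, name = "v"),
    list(type = "quadratic", var = "v", scale = c(0, 1), beta = 0.1,
         name = "v2")), continuous = "v", ranges = list(v = c(0, 1)),
    categorical = NULL, n_presence = 10), class = "rh_features")
  Xb <- feature_matrix(fsq, bgq)
  lam <- c(4, -4)  # vertex at v = 0.5 on the scaled axis
  mq <- structure(list(features = fsq, lambda = lam,
                       logZ = ravinehab:::log_sum_exp(Xb %*% lam),
                       entropy = 2, rm = 1, bg_data = bgq, converged = TRUE),
                  class = "rh_maxent")
  rq <- response_curve(mq, "v", n_points = 101)
  expect_equal(rq$x[which.max(rq$cloglog)], 0.5, tolerance = 0.02)
})

test_that("evaluation_report assembles consistent pieces", {
  set.seed(41)
  bg <- data.frame(v = runif(200), u = runif(200))
  pres <- data.frame(v = runif(30, 0.6, 1), u = runif(30))
  cv <- crossvalidate(pres, bg, k = 3, seed = 2, classes = "L",
                      categorical = NULL)
  fs <- make_features(rbind(pres, bg), 30, classes = "L", categorical = NULL)
  m <- fit_maxent(fs, pres, bg)
  rep <- evaluation_report(cv, m, pres, bg, seed = 1)
  expect_true(rep$tss >= -1 && rep$tss <= 1)
  expect_true(rep$sedi >= -1 && rep$sedi <= 1)
  expect_equal(sum(unlist(rep$importance)), 100, tolerance = 0.1)
  expect_equal(sum(unlist(rep$contribution)), 100, tolerance = 0.1)
  expect_true(rep$auc_class %in% c("outstanding", "excellent", "acceptable",
                                   "poor", "invalid"))
})
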