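# Presence-background maximum-entropy model, implemented from scratch:
# feature expansion (linear, quadratic, product, hinge, categorical
# indicators), bias-matched background sampling, monotone proximal-gradient
# optimization of the L1-regularized log loss, raw/cloglog prediction, AICc
# model selection and k-fold cross-validation.

#' Sample bias-matched background points
#'
#' Background cells are restricted to landform classes 6-10 (the potential
#' stream valleys that occurrences are snapped into) and drawn without
#' replacement with probability proportional to `exp(-d_road / tau)`, which
#' concentrates them near roads the way opportunistic sampling does.
#' `tau = Inf` gives a uniform draw over the eligible cells.
#'
#' @param n number of points (default 10000).
#' @param landform categorical landform `rh_grid`.
#' @param roads_dist `rh_grid` of distance to roads (m).
#' @param tau road-bias decay length in meters.
#' @param seed RNG seed.
#' @param classes eligible landform codes.
#' @return list with `cells` (row, col matrix) and `xy` coordinates.
#' @export
sample_background <- function(n = 10000, landform, roads_dist, tau = Inf,
                              seed = 1, classes = 6:10) {
  elig <- which(!is.na(landform$values) & landform$values %in% classes)
  if (length(elig) == 0) stop("no cells in the eligible landform classes")
  d <- roads_dist$values[elig]
  w <- if (is.infinite(tau)) rep(1, length(elig)) else exp(-d / tau)
  if (length(elig) <= n) {
    if (length(elig) < n)
      warning(sprintf("only %d eligible cells for %d requested background points",
                      length(elig), n))
    pick <- elig
  } else {
    pick <- with_seed(seed, sample(elig, n, prob = w))
  }
  nr <- nrow(landform$values)
  cells <- cbind(row = ((pick - 1L) %% nr) + 1L,
                 col = ((pick - 1L) %/% nr) + 1L)
  list(cells = cells, xy = cell_center_xy(landform, cells[, 1], cells[, 2]))
}

#' Build a maxent feature set from covariate samples
#'
#' Feature classes: `L` linear, `Q` quadratic, `P` pairwise products of
#' continuous variables, `H` forward and reverse hinges at `n_hinge`
#' empirical-quantile knots per variable.  Categorical variables expand to
#' one indicator per observed class.  Every feature is scaled to \[0, 1\]
#' using the pooled presence+background range; constant variables are
#' dropped.  Default regularization weights follow feature class: linear /
#' quadratic / product `1/sqrt(m)` (m = presence count), hinge 0.5,
#' categorical 0.25.
#'
#' @param data data.frame of covariate values at presences and background.
#' @param n_presence presence count m used for the L/Q/P weight.
#' @param classes subset of `c("L","Q","H","P")`.
#' @param n_hinge hinge knots per variable and direction.
#' @param categorical names of categorical columns.
#' @return an `rh_features` object.
#' @export
make_features <- function(data, n_presence, classes = c("L", "Q", "H", "P"),
                          n_hinge = 50, categorical = "landform") {
  classes <- match.arg(classes, several.ok = TRUE)
  cont <- setdiff(names(data), categorical)
  rng <- lapply(data[cont], range, na.rm = TRUE)
  keep <- vapply(rng, function(r) diff(r) > 0, TRUE)
  cont <- cont[keep]
  rng <- rng[keep]
  beta_lqp <- 1 / sqrt(max(n_presence, 1))
  defs <- list()
  add <- function(d) defs[[length(defs) + 1L]] <<- d
  sc_range <- function(v) range(v, na.rm = TRUE)
  for (v in cont) {
    x <- data[[v]]
    if ("L" %in% classes)
      add(list(type = "linear", var = v, scale = rng[[v]], beta = beta_lqp,
               name = v))
    if ("Q" %in% classes)
      add(list(type = "quadratic", var = v, scale = sc_range(x^2),
               beta = beta_lqp, name = paste0(v, "^2")))
    if ("H" %in% classes) {
      qs <- stats::quantile(x, probs = seq_len(n_hinge) / (n_hinge + 1),
                            na.rm = TRUE, names = FALSE)
      qs <- unique(qs[qs > rng[[v]][1] & qs < rng[[v]][2]])
      for (k in qs) {
        add(list(type = "hinge_fwd", var = v, knot = k, scale = rng[[v]],
                 beta = 0.5, name = sprintf("h(%s>%.4g)", v, k)))
        add(list(type = "hinge_rev", var = v, knot = k, scale = rng[[v]],
                 beta = 0.5, name = sprintf("h(%s<%.4g)", v, k)))
      }
    }
  }
  if ("P" %in% classes && length(cont) >= 2) {
    for (i in seq_along(cont)) for (j in seq_along(cont)) {
      if (j <= i) next
      prod <- data[[cont[i]]] * data[[cont[j]]]
      add(list(type = "product", var = cont[i], var2 = cont[j],
               scale = sc_range(prod), beta = beta_lqp,
               name = paste0(cont[i], "*", cont[j])))
    }
  }
  for (v in intersect(categorical, names(data))) {
    for (cl in sort(unique(data[[v]][!is.na(data[[v]])])))
      add(list(type = "indicator", var = v, level = cl, beta = 0.25,
               name = sprintf("%s==%g", v, cl)))
  }
  structure(list(defs = defs, continuous = cont, ranges = rng,
                 categorical = categorical, n_presence = n_presence),
            class = "rh_features")
}

#' @export
print.rh_features <- function(x, ...) {
  types <- table(vapply(x$defs, `[[`, "", "type"))
  cat(sprintf("<rh_features> %d features (%s)\n", length(x$defs),
              paste(names(types), types, sep = ":", collapse = ", ")))
  invisible(x)
}

scale01 <- function(v, r) {
  if (diff(r) <= 0) return(v * 0)
  pmin(pmax((v - r[1]) / (r[2] - r[1]), 0), 1)
}

#' Evaluate a feature set on covariate rows
#'
#' @param fs an `rh_features`.
#' @param data covariate data.frame.
#' @param clamp clamp continuous variables to their training range.
#' @return numeric matrix, one column per feature, values in \[0, 1\].
#' @export
feature_matrix <- function(fs, data, clamp = FALSE) {
  if (clamp) {
    clamped <- FALSE
    for (v in fs$continuous) {
      r <- fs$ranges[[v]]
      out_of <- !is.na(data[[v]]) & (data[[v]] < r[1] | data[[v]] > r[2])
      if (any(out_of)) clamped <- TRUE
      data[[v]] <- pmin(pmax(data[[v]], r[1]), r[2])
    }
    if (clamped) warning("values outside the training range were clamped")
  }
  cols <- lapply(fs$defs, function(d) {
    switch(d$type,
           linear = scale01(data[[d$var]], d$scale),
           quadratic = scale01(data[[d$var]]^2, d$scale),
           product = scale01(data[[d$var]] * data[[d$var2]], d$scale),
           hinge_fwd = pmax(0, data[[d$var]] - d$knot) /
             (d$scale[2] - d$knot),
           hinge_rev = pmax(0, d$knot - data[[d$var]]) /
             (d$knot - d$scale[1]),
           indicator = as.numeric(data[[d$var]] == d$level))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(fs$defs, `[[`, "", "name")
  m
}

log_sum_exp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Fit the maxent model by monotone proximal-gradient descent
#'
#' Minimizes `-mean_presence(f.lambda) + log sum_background exp(f.lambda)
#' + rm * sum_j beta_j |lambda_j|` (a convex problem) with backtracking line
#' search; the objective decreases monotonically.  Convergence is declared
#' when the L1 subgradient optimality conditions hold to `tol`.
#'
#' @param fs an `rh_features`.
#' @param pres_data,bg_data covariate data.frames for presences/background.
#' @param rm regularization multiplier (default 1).
#' @param tol gradient tolerance (default 1e-6).
#' @param max_iter iteration cap.
#' @return an `rh_maxent` model.
#' @export
fit_maxent <- function(fs, pres_data, bg_data, rm = 1, tol = 1e-6,
                       max_iter = 5000) {
  if (nrow(pres_data) < 2) stop("need at least 2 presences")
  Xp <- feature_matrix(fs, pres_data)
  Xb <- feature_matrix(fs, bg_data)
  ok_p <- stats::complete.cases(Xp); ok_b <- stats::complete.cases(Xb)
  Xp <- Xp[ok_p, , drop = FALSE]; Xb <- Xb[ok_b, , drop = FALSE]
  p <- ncol(Xb)
  beta <- vapply(fs$defs, `[[`, 0, "beta")
  pen <- rm * beta
  mp <- colMeans(Xp)
  lam <- rep(0, p)
  smooth <- function(l) {
    eta <- as.vector(Xb %*% l)
    -sum(mp * l) + log_sum_exp(eta)
  }
  gradient <- function(l) {
    eta <- as.vector(Xb %*% l)
    w <- exp(eta - log_sum_exp(eta))
    -mp + as.vector(crossprod(Xb, w))
  }
  obj <- function(l) smooth(l) + sum(pen * abs(l))
  step <- 1
  f <- smooth(lam)
  trace <- obj(lam)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- gradient(lam)
    # subgradient optimality check
    viol <- ifelse(lam != 0, abs(g + pen * sign(lam)),
                   pmax(abs(g) - pen, 0))
    if (max(viol) < tol) { converged <- TRUE; break }
    repeat {
      cand <- lam - step * g
      cand <- sign(cand) * pmax(abs(cand) - step * pen, 0)  # soft threshold
      fc <- smooth(cand)
      dlt <- cand - lam
      if (fc <= f + sum(g * dlt) + sum(dlt^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    lam <- cand
    f <- fc
    trace <- c(trace, obj(lam))
    step <- step * 1.25
  }
  if (!converged && max_iter > 100)
    warning(sprintf("fit_maxent: not converged after %d iterations (max KKT violation %.2e)",
                    max_iter, max(viol)))
  eta_b <- as.vector(Xb %*% lam)
  logZ <- log_sum_exp(eta_b)
  raw_b <- exp(eta_b - logZ)
  H <- -sum(raw_b * log(pmax(raw_b, 1e-300)))
  structure(list(features = fs, lambda = stats::setNames(lam, colnames(Xb)),
                 rm = rm, logZ = logZ, entropy = H,
                 bg_data = bg_data[ok_b, , drop = FALSE],
                 objective_trace = trace, converged = converged),
            class = "rh_maxent")
}

#' @export
print.rh_maxent <- function(x, ...) {
  cat(sprintf("<rh_maxent> %d features, %d nonzero, rm = %g, H = %.3f%s\n",
              length(x$lambda), sum(x$lambda != 0), x$rm, x$entropy,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predict from a fitted maxent model
#'
#' `raw` is the exponential-family density normalized to sum to 1 over the
#' training background; `cloglog = 1 - exp(-exp(H) * raw)` where `H` is the
#' entropy of the raw distribution over background.  Covariates outside the
#' training range are clamped with a warning.
#'
#' @param object an `rh_maxent`.
#' @param newdata covariate data.frame.
#' @param output `"cloglog"`, `"raw"`, or `"link"` (linear predictor).
#' @param ... unused.
#' @return numeric vector (NA where covariates are NA).
#' @export
predict.rh_maxent <- function(object, newdata, output = "cloglog", ...) {
  X <- feature_matrix(object$features, newdata, clamp = TRUE)
  eta <- as.vector(X %*% object$lambda)
  if (output == "link") return(eta)
  raw <- exp(eta - object$logZ)
  if (output == "raw") return(raw)
  1 - exp(-exp(object$entropy) * raw)
}

#' Predict a suitability map over a covariate stack
#'
#' @param model an `rh_maxent`.
#' @param stack an `rh_stack`.
#' @param output passed to [predict.rh_maxent()].
#' @return an `rh_grid`.
#' @export
predict_map <- function(model, stack, output = "cloglog") {
  g1 <- stack$layers[[1]]
  nr <- nrow(g1$values); nc <- ncol(g1$values)
  cells <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  df <- stack_extract(stack, cells = cells)
  ok <- stats::complete.cases(df)
  vals <- rep(NA_real_, nrow(df))
  if (any(ok))
    vals[ok] <- suppressWarnings(predict(model, df[ok, , drop = FALSE],
                                         output = output))
  grid_create(matrix(vals, nr, nc), g1$cell_size, g1$origin_x, g1$origin_y)
}

#' AICc of a maxent model
#'
#' The raw prediction is renormalized to sum to 1 over the evaluation
#' landscape; `logL` is the summed log of the normalized raw values at the
#' presences, `k` counts nonzero coefficients, and
#' `AICc = 2k - 2 logL + 2k(k+1)/(n-k-1)`, undefined when `n <= k + 1`.
#'
#' @param model an `rh_maxent`.
#' @param pres_data presence covariates.
#' @param landscape_data evaluation landscape (default: training background).
#' @return list with `k`, `logL`, `aicc` (NA when undefined), `n`.
#' @export
aicc <- function(model, pres_data, landscape_data = NULL) {
  if (is.null(landscape_data)) landscape_data <- model$bg_data
  raw_land <- suppressWarnings(predict(model, landscape_data, output = "raw"))
  raw_pres <- suppressWarnings(predict(model, pres_data, output = "raw"))
  Z <- sum(raw_land, na.rm = TRUE)
  logL <- sum(log(raw_pres / Z))
  k <- sum(model$lambda != 0)
  n <- nrow(pres_data)
  val <- if (n > k + 1) 2 * k - 2 * logL + 2 * k * (k + 1) / (n - k - 1)
  else NA_real_
  list(k = k, logL = logL, aicc = val, n = n)
}

#' Fit candidate models and select the lowest-AICc one
#'
#' Candidates are the cross of regularization multipliers and feature-class
#' sets.  Ties break toward fewer nonzero coefficients, then the smaller
#' multiplier.
#'
#' @param pres_data,bg_data covariate data.frames.
#' @param rm_grid regularization multipliers to try.
#' @param class_grid list of feature-class sets.
#' @param n_hinge hinge knots per variable.
#' @param categorical categorical covariate names.
#' @param ... passed to [fit_maxent()].
#' @return list with `model` (winner), `records` (selection table),
#'   `best` (winning row index).
#' @export
select_model <- function(pres_data, bg_data, rm_grid = c(0.5, 1, 2),
                         class_grid = list("L", c("L", "Q"),
                                           c("L", "Q", "H"),
                                           c("L", "Q", "H", "P")),
                         n_hinge = 50, categorical = "landform", ...) {
  fits <- list(); recs <- list()
  for (cl in class_grid) for (rm in rm_grid) {
    fs <- make_features(rbind(pres_data, bg_data), nrow(pres_data),
                        classes = cl, n_hinge = n_hinge,
                        categorical = categorical)
    m <- fit_maxent(fs, pres_data, bg_data, rm = rm, ...)
    a <- aicc(m, pres_data)
    fits[[length(fits) + 1]] <- m
    recs[[length(recs) + 1]] <- data.frame(
      rm = rm, classes = paste(cl, collapse = ""), k = a$k, logL = a$logL,
      aicc = a$aicc)
  }
  records <- do.call(rbind, recs)
  if (all(is.na(records$aicc))) stop("AICc undefined for every candidate")
  ord <- order(records$aicc, records$k, records$rm, na.last = TRUE)
  best <- ord[1]
  list(model = fits[[best]], records = records, best = best)
}

#' k-fold cross-validation of the maxent model
#'
#' Presences are partitioned into `k` random folds (background is shared
#' across folds, as in Maxent); one model is fitted per fold on the
#' remaining presences.  Held-out presence scores are pooled across folds
#' and background scores are averaged over the fold models; when a stack is
#' given the per-fold cloglog maps are averaged into `mean_map`.
#'
#' @param pres_data,bg_data covariate data.frames.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param classes,n_hinge,categorical feature setup.
#' @param rm regularization multiplier.
#' @param stack optional `rh_stack` for the averaged map.
#' @param ... passed to [fit_maxent()].
#' @return list with `models`, `fold`, `pos_scores` (held-out presences),
#'   `neg_scores` (background, averaged), `train_auc`, `test_auc` per fold,
#'   and `mean_map`.
#' @export
crossvalidate <- function(pres_data, bg_data, k = 10, seed = 1,
                          classes = c("L", "Q", "H", "P"), n_hinge = 50,
                          categorical = "landform", rm = 1, stack = NULL,
                          ...) {
  n <- nrow(pres_data)
  if (k > n) stop("k exceeds the number of presences")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  models <- vector("list", k)
  pos_scores <- rep(NA_real_, n)
  neg_mat <- matrix(NA_real_, nrow(bg_data), k)
  train_auc <- test_auc <- numeric(k)
  map_sum <- NULL
  for (f in seq_len(k)) {
    tr <- pres_data[fold != f, , drop = FALSE]
    te <- pres_data[fold == f, , drop = FALSE]
    fs <- make_features(rbind(tr, bg_data), nrow(tr), classes = classes,
                        n_hinge = n_hinge, categorical = categorical)
    m <- fit_maxent(fs, tr, bg_data, rm = rm, ...)
    models[[f]] <- m
    sc_te <- suppressWarnings(predict(m, te))
    sc_tr <- suppressWarnings(predict(m, tr))
    sc_bg <- suppressWarnings(predict(m, bg_data))
    pos_scores[fold == f] <- sc_te
    neg_mat[, f] <- sc_bg
    train_auc[f] <- roc_auc(sc_tr, sc_bg)
    test_auc[f] <- if (nrow(te)) roc_auc(sc_te, sc_bg) else NA_real_
    if (!is.null(stack)) {
      mp <- predict_map(m, stack)
      map_sum <- if (is.null(map_sum)) mp$values else map_sum + mp$values
    }
  }
  mean_map <- if (is.null(stack)) NULL else {
    g1 <- stack$layers[[1]]
    grid_create(map_sum / k, g1$cell_size, g1$origin_x, g1$origin_y)
  }
  list(models = models, fold = fold, pos_scores = pos_scores,
       neg_scores = rowMeans(neg_mat), train_auc = train_auc,
       test_auc = test_auc, mean_map = mean_map)
}

#' Serialize / restore a maxent model as JSON
#'
#' @param model an `rh_maxent`.
#' @param path output path.
#' @export
maxent_write_json <- function(model, path) {
  fs <- model$features
  out <- list(
    defs = fs$defs, continuous = fs$continuous, ranges = fs$ranges,
    categorical = fs$categorical, n_presence = fs$n_presence,
    lambda = as.list(model$lambda), rm = model$rm, logZ = model$logZ,
    entropy = model$entropy)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname maxent_write_json
#' @export
maxent_read_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fs <- structure(list(
    defs = lapply(j$defs, function(d) { d$scale <- unlist(d$scale); d }),
    continuous = unlist(j$continuous),
    ranges = lapply(j$ranges, unlist),
    categorical = unlist(j$categorical), n_presence = j$n_presence),
    class = "rh_features")
  structure(list(features = fs, lambda = unlist(j$lambda), rm = j$rm,
                 logZ = j$logZ, entropy = j$entropy, bg_data = NULL,
                 objective_trace = NULL, converged = TRUE),
            class = "rh_maxent")
}
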