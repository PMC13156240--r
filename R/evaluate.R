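# Threshold-independent and threshold-dependent model evaluation: ROC/AUC,
# equal-sensitivity/specificity threshold, TSS, SEDI, accuracy, permutation
# importance, percent contribution, and response curves.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `P(pos > neg) + 0.5 P(pos == neg)` over all presence/background pairs;
#' invariant under strictly monotone transforms of the scores.
#'
#' @param pos_scores,neg_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score sets must be non-empty")
  r <- rank(c(pos_scores, neg_scores))
  np <- length(pos_scores); nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Hosmer-style AUC class label
#'
#' outstanding (> 0.90), excellent (0.80-0.90), acceptable (0.70-0.79),
#' poor (0.50-0.69), invalid (< 0.50).
#'
#' @param auc AUC value.
#' @return character label.
#' @export
auc_class <- function(auc) {
  if (auc > 0.90) "outstanding"
  else if (auc >= 0.80) "excellent"
  else if (auc >= 0.70) "acceptable"
  else if (auc >= 0.50) "poor"
  else "invalid"
}

#' Equal-sensitivity/specificity threshold
#'
#' Candidate thresholds are midpoints of consecutive sorted unique scores
#' (plus just-below-minimum and just-above-maximum); the one minimizing
#' `|sensitivity - specificity|` is returned, ties resolving to the lowest.
#'
#' @param pos_scores,neg_scores numeric score vectors.
#' @return the threshold.
#' @export
ess_threshold <- function(pos_scores, neg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score sets must be non-empty")
  s <- sort(unique(c(pos_scores, neg_scores)))
  cand <- if (length(s) == 1) s else
    c(s[1] - 1e-9, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1e-9)
  gap <- vapply(cand, function(t) {
    sens <- mean(pos_scores >= t)
    spec <- mean(neg_scores < t)
    abs(sens - spec)
  }, 0)
  cand[which.min(gap)]  # which.min returns the first (lowest) minimizer
}

#' Threshold-dependent skill metrics: TSS, SEDI, accuracy
#'
#' With hit rate `H` = sensitivity and false-alarm rate `F` =
#' 1 - specificity: `TSS = H - F`;
#' `SEDI = (ln F - ln H - ln(1-F) + ln(1-H)) / (ln F + ln H + ln(1-F) + ln(1-H))`
#' with `H` and `F` clamped into `[eps, 1-eps]`, `eps = 1/(2n)` of the
#' respective sample, to keep the logs finite; accuracy is the fraction of
#' correctly classified points (background as pseudo-absence).
#'
#' @param pos_scores,neg_scores numeric score vectors.
#' @param threshold scores `>= threshold` predict presence.
#' @return list with `tss`, `sedi`, `accuracy`, `sensitivity`,
#'   `specificity`, and the confusion counts.
#' @export
confusion_metrics <- function(pos_scores, neg_scores, threshold) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score sets must be non-empty")
  if (!is.finite(threshold)) stop("threshold must be finite")
  tp <- sum(pos_scores >= threshold); fn <- length(pos_scores) - tp
  fp <- sum(neg_scores >= threshold); tn <- length(neg_scores) - fp
  H <- tp / (tp + fn)
  FF <- fp / (fp + tn)
  tss <- H - FF
  clamp <- function(x, n) pmin(pmax(x, 1 / (2 * n)), 1 - 1 / (2 * n))
  Hc <- clamp(H, length(pos_scores)); Fc <- clamp(FF, length(neg_scores))
  sedi <- (log(Fc) - log(Hc) - log(1 - Fc) + log(1 - Hc)) /
    (log(Fc) + log(Hc) + log(1 - Fc) + log(1 - Hc))
  list(tss = tss, sedi = sedi,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = H, specificity = 1 - FF,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Permutation importance of each covariate
#'
#' Per variable: shuffle its values across all presence+background rows,
#' rescore, and record the drop in training AUC; drops are averaged over
#' `reps`, floored at zero, and normalized to sum to 100.
#'
#' @param model an `rh_maxent`.
#' @param pres_data,bg_data covariate data.frames.
#' @param seed RNG seed.
#' @param reps shuffles per variable.
#' @return named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, pres_data, bg_data, seed = 1,
                                   reps = 10) {
  vars <- c(model$features$continuous,
            intersect(model$features$categorical, names(pres_data)))
  np <- nrow(pres_data)
  all_data <- rbind(pres_data, bg_data)
  base_pos <- suppressWarnings(predict(model, pres_data, output = "link"))
  base_neg <- suppressWarnings(predict(model, bg_data, output = "link"))
  base_auc <- roc_auc(base_pos, base_neg)
  drops <- with_seed(seed, {
    vapply(vars, function(v) {
      mean(vapply(seq_len(reps), function(r) {
        shuf <- all_data
        shuf[[v]] <- sample(shuf[[v]])
        sc <- suppressWarnings(predict(model, shuf, output = "link"))
        base_auc - roc_auc(sc[seq_len(np)], sc[-seq_len(np)])
      }, 0))
    }, 0)
  })
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    warning("no variable affects the AUC; importance reported as uniform")
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * drops / sum(drops)
}

#' Percent contribution of each covariate
#'
#' Accumulates, per variable, `|lambda_j| * sd_j` of its features over the
#' training background and normalizes to 100.  This weights each feature by
#' how much its term actually varies across the landscape (a simplification
#' of Maxent's training-path accounting).
#'
#' @param model an `rh_maxent` (with training background attached).
#' @param bg_data optional background override.
#' @return named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model, bg_data = NULL) {
  if (is.null(bg_data)) bg_data <- model$bg_data
  X <- feature_matrix(model$features, bg_data)
  sds <- apply(X, 2, stats::sd)
  fvar <- vapply(model$features$defs, `[[`, "", "var")
  vars <- unique(c(model$features$continuous,
                   intersect(model$features$categorical, fvar)))
  contrib <- vapply(vars, function(v) {
    j <- which(fvar == v |
                 vapply(model$features$defs, function(d)
                   identical(d$var2, v), TRUE))
    sum(abs(model$lambda[j]) * sds[j])
  }, 0)
  if (sum(contrib) == 0) {
    warning("all coefficients are zero; contribution reported as uniform")
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * contrib / sum(contrib)
}

#' Response curve of one variable
#'
#' Sweeps `variable` over its background range while other continuous
#' variables sit at their background mean and categorical ones at their
#' mode.
#'
#' @param model an `rh_maxent`.
#' @param variable covariate name.
#' @param n_points sweep resolution.
#' @param bg_data optional background override.
#' @return data.frame with columns `x` and `cloglog`.
#' @export
response_curve <- function(model, variable, n_points = 100, bg_data = NULL) {
  if (is.null(bg_data)) bg_data <- model$bg_data
  ref <- as.data.frame(lapply(names(bg_data), function(v) {
    col <- bg_data[[v]]
    if (v %in% model$features$categorical) {
      tb <- table(col)
      rep(as.numeric(names(tb)[which.max(tb)]), n_points)
    } else rep(mean(col, na.rm = TRUE), n_points)
  }))
  names(ref) <- names(bg_data)
  xs <- seq(min(bg_data[[variable]], na.rm = TRUE),
            max(bg_data[[variable]], na.rm = TRUE), length.out = n_points)
  ref[[variable]] <- xs
  data.frame(x = xs,
             cloglog = suppressWarnings(predict(model, ref,
                                                output = "cloglog")))
}

#' Assemble the full evaluation report
#'
#' @param cv result of [crossvalidate()].
#' @param model the full-data `rh_maxent` used for importance/contribution.
#' @param pres_data,bg_data covariate data.frames.
#' @param seed RNG seed for the permutation importance.
#' @return an `rh_evaluation` list (JSON-serializable).
#' @export
evaluation_report <- function(cv, model, pres_data, bg_data, seed = 1) {
  thr <- ess_threshold(cv$pos_scores, cv$neg_scores)
  cm <- confusion_metrics(cv$pos_scores, cv$neg_scores, thr)
  imp <- permutation_importance(model, pres_data, bg_data, seed = seed)
  pc <- percent_contribution(model, bg_data)
  structure(list(
    auc_train_mean = mean(cv$train_auc), auc_train_sd = stats::sd(cv$train_auc),
    auc_test_mean = mean(cv$test_auc, na.rm = TRUE),
    auc_test_sd = stats::sd(cv$test_auc, na.rm = TRUE),
    auc_class = auc_class(mean(cv$test_auc, na.rm = TRUE)),
    threshold_ess = thr,
    tss = cm$tss, sedi = cm$sedi, accuracy = cm$accuracy,
    confusion = cm[c("tp", "fp", "tn", "fn")],
    importance = as.list(imp), contribution = as.list(pc)),
    class = "rh_evaluation")
}

#' @export
print.rh_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<rh_evaluation> train AUC %.3f +/- %.3f, ",
                     "test AUC %.3f +/- %.3f (%s)\n",
                     "  ESS threshold %.3f: TSS %.3f, SEDI %.3f, accuracy %.3f\n"),
              x$auc_train_mean, x$auc_train_sd, x$auc_test_mean,
              x$auc_test_sd, x$auc_class, x$threshold_ess, x$tss, x$sedi,
              x$accuracy))
  invisible(x)
}
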