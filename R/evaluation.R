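#' Binary task labels from cohort groups
#'
#' The two study tasks are detecting cognitive impairment (`CI_vs_HC`: MCI
#' and AD merged into CI, positive class CI, against HC) and separating the
#' impairment stages (`AD_vs_MCI`: positive class AD). Subjects outside the
#' task's classes are dropped via `keep`.
#'
#' @param groups group label per subject (HC/MCI/AD by default).
#' @param task `"CI_vs_HC"` or `"AD_vs_MCI"`.
#' @param positive override the positive class label.
#' @return List with `keep` (row indices), `labels` (character vector over
#'   kept rows) and `positive`.
#' @export
task_labels <- function(groups, task = c("CI_vs_HC", "AD_vs_MCI"),
                        positive = NULL) {
  task <- match.arg(task)
  groups <- as.character(groups)
  if (task == "CI_vs_HC") {
    keep <- which(groups %in% c("HC", "MCI", "AD"))
    labels <- ifelse(groups[keep] == "HC", "HC", "CI")
    positive <- positive %||% "CI"
  } else {
    keep <- which(groups %in% c("MCI", "AD"))
    labels <- groups[keep]
    positive <- positive %||% "AD"
  }
  if (!positive %in% labels) stop("positive class absent from labels")
  list(keep = keep, labels = labels, positive = positive)
}

#' Stratified cross-validation / test split plan
#'
#' Splits subjects into a cross-validation portion and a held-out test
#' portion at `ratio` (cv:test, default 2:1), stratified by class; the test
#' count per class is `floor(n_class * test_fraction)` and the remainder goes
#' to the cross-validation portion. The cv portion is then divided into
#' `n_folds` stratified folds whose per-class sizes differ by at most one.
#' Seeded and reproducible.
#'
#' @param labels class label per subject.
#' @param ratio length-2 numeric, cv:test proportions.
#' @param n_folds number of folds over the cv portion.
#' @param seed integer seed.
#' @param ids subject identifiers; default positional indices.
#' @return Object of class `split_plan`: `cv_ids`, `test_ids`, `folds`
#'   (named fold index per cv id), `seed`, `ratio`, `n_folds`.
#' @export
make_split <- function(labels, ratio = c(2, 1), n_folds = 10, seed = 1,
                       ids = NULL) {
  labels <- as.character(labels)
  if (is.null(ids)) ids <- seq_along(labels)
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  if (length(ratio) != 2 || any(ratio < 0) || sum(ratio) <= 0) {
    stop("ratio must be two nonnegative proportions")
  }
  test_frac <- ratio[2] / sum(ratio)
  if (test_frac <= 0) stop("test portion is empty: ratio must give it mass")
  cls <- sort(unique(labels))
  cv_ids <- test_ids <- c()
  folds <- integer(0)
  with_seed(seed, {
    for (cl in cls) {
      members <- ids[labels == cl]
      n_c <- length(members)
      n_test <- floor(n_c * test_frac)
      if (n_test < 1) {
        stop(sprintf("class '%s' too small for a %g:%g split (n = %d)",
                     cl, ratio[1], ratio[2], n_c))
      }
      n_cv <- n_c - n_test
      if (n_cv < n_folds) {
        stop(sprintf(
          "class '%s' too small: %d cv subjects for %d folds", cl, n_cv,
          n_folds))
      }
      perm <- sample(members)
      test_ids <- c(test_ids, perm[seq_len(n_test)])
      cv_cl <- perm[(n_test + 1):n_c]
      f <- rep(seq_len(n_folds), length.out = n_cv)
      folds <- c(folds, setNames(f, cv_cl))
      cv_ids <- c(cv_ids, cv_cl)
    }
  })
  structure(list(cv_ids = cv_ids, test_ids = test_ids, folds = folds,
                 seed = seed, ratio = ratio, n_folds = n_folds),
            class = "split_plan")
}

#' Diagnostic metrics from confusion counts
#'
#' @param tp,fn,tn,fp confusion counts (positives down the `tp`/`fn` margin).
#' @return Named numeric: accuracy, sensitivity, specificity, ppv, npv.
#'   Undefined ratios (zero denominator) are `NA` with a warning.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: empty denominator", what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  c(accuracy = ratio(tp + tn, tp + tn + fp + fn, "accuracy"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    ppv = ratio(tp, tp + fp, "PPV"),
    npv = ratio(tn, tn + fn, "NPV"))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (predict positive when
#' `score >= t`), returns the (FPR, TPR) points anchored at (0,0) and (1,1),
#' and computes AUC by the trapezoid rule, which on these points equals the
#' Mann-Whitney pair-counting statistic with ties counted one half.
#'
#' @param scores continuous scores, higher = more positive.
#' @param labels class per score.
#' @param positive positive class label.
#' @return List with `points` (data frame threshold/fpr/tpr) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  is_pos <- as.character(labels) == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes to be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  # collapse tied scores so each unique value is one operating point
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(threshold = s[last],
                    fpr = fp[last] / n_neg,
                    tpr = tp[last] / n_pos)
  pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

# build an evaluation report from pooled predictions
make_report <- function(truth, predicted, score_pos, positive, settings,
                        what) {
  is_pos <- truth == positive
  tp <- sum(predicted == positive & is_pos)
  fn <- sum(predicted != positive & is_pos)
  tn <- sum(predicted != positive & !is_pos)
  fp <- sum(predicted == positive & !is_pos)
  metrics <- confusion_metrics(tp, fn, tn, fp)
  roc <- if (sum(is_pos) > 0 && sum(!is_pos) > 0) {
    roc_curve(score_pos, truth, positive)
  } else NULL
  structure(list(what = what,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 metrics = metrics,
                 auc = if (is.null(roc)) NA_real_ else roc$auc,
                 roc = roc$points,
                 predictions = data.frame(truth = truth,
                                          predicted = predicted,
                                          score = score_pos,
                                          stringsAsFactors = FALSE),
                 positive = positive, settings = settings,
                 intervals = NULL),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s; positive = %s)\n", x$what, x$positive))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n", x$confusion["tp"],
              x$confusion["fn"], x$confusion["tn"], x$confusion["fp"]))
  m <- x$metrics
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
              m["accuracy"], m["sensitivity"], m["specificity"], m["ppv"],
              m["npv"]))
  cat(sprintf("  AUC %.3f\n", x$auc))
  if (!is.null(x$intervals)) {
    cat(sprintf("  repeat intervals (%d repeats, 2.5/97.5%%):\n",
                x$intervals$repeats))
    iv <- x$intervals$table
    for (i in seq_len(nrow(iv))) {
      cat(sprintf("    %-11s [%.3f %.3f]\n", iv$metric[i], iv$low[i],
                  iv$high[i]))
    }
  }
  invisible(x)
}

# one pass of pooled k-fold cross-validation under a given plan
cv_once <- function(fm, labels, plan, settings, positive, seed) {
  idx_of <- setNames(seq_len(nrow(fm$x)), fm$subject_id)
  truth <- predicted <- character(0)
  score <- numeric(0)
  classes <- c(positive, setdiff(sort(unique(labels)), positive))
  for (f in seq_len(plan$n_folds)) {
    held <- names(plan$folds)[plan$folds == f]
    train <- setdiff(plan$cv_ids, held)
    tr_rows <- idx_of[as.character(train)]
    te_rows <- idx_of[as.character(held)]
    tr_labs <- labels[tr_rows]
    if (length(unique(tr_labs)) < 2) {
      stop(sprintf("fold %d leaves a single-class training partition", f))
    }
    model <- src_fit(fm, labels, rows = tr_rows, settings = settings,
                     classes = classes, seed = seed * 1000L + f)
    pr <- src_predict(model, fm, rows = te_rows)
    truth <- c(truth, labels[te_rows])
    predicted <- c(predicted, pr$predicted)
    # classify() scores positive toward class 2; class 1 here is `positive`
    score <- c(score, -pr$score)
  }
  list(truth = truth, predicted = predicted, score = score)
}

#' Pooled stratified k-fold cross-validation of the sparse model
#'
#' For each fold the imputer, normalizer, screening and dictionary are
#' re-fit on the nine training folds only, the held-out fold is classified,
#' and predictions are pooled over folds into one confusion matrix and ROC.
#' With `repeats > 1` the whole procedure is repeated under derived seeds
#' (fold reshuffling and screening resampling) and 2.5/97.5 percentile
#' intervals of each metric are attached; the reported point values are the
#' means over repeats.
#'
#' @param fm a `feature_matrix`.
#' @param labels two-class vector per row of `fm`.
#' @param plan a [make_split()] plan covering `fm`'s subjects.
#' @param settings a [src_settings()] list.
#' @param positive positive class label (default first sorted class).
#' @param repeats number of seeded repetitions (default 1).
#' @return An `evaluation_report` (predictions/ROC from the first repeat).
#' @export
run_cv <- function(fm, labels, plan, settings = src_settings(),
                   positive = sort(unique(as.character(labels)))[1],
                   repeats = 1) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(plan, "split_plan"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(fm$x))
  reports <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    plan_r <- plan
    if (r > 1) {
      # reshuffle folds over the same cv subjects, stratified by class
      plan_r$folds <- with_seed(plan$seed + r, {
        f <- integer(0)
        cv_labs <- labels[match(plan$cv_ids, fm$subject_id)]
        for (cl in sort(unique(cv_labs))) {
          members <- sample(plan$cv_ids[cv_labs == cl])
          f <- c(f, setNames(rep(seq_len(plan$n_folds),
                                 length.out = length(members)), members))
        }
        f
      })
    }
    pooled <- cv_once(fm, labels, plan_r, settings, positive,
                      seed = plan$seed + r)
    reports[[r]] <- make_report(pooled$truth, pooled$predicted, pooled$score,
                                positive, settings, "10-fold CV (pooled)")
  }
  out <- reports[[1]]
  if (repeats > 1) {
    tab <- t(vapply(reports, function(rep) c(rep$metrics, auc = rep$auc),
                    numeric(6)))
    out$metrics <- colMeans(tab[, 1:5, drop = FALSE], na.rm = TRUE)
    out$auc <- mean(tab[, "auc"], na.rm = TRUE)
    qs <- apply(tab, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    out$intervals <- list(repeats = repeats,
                          table = data.frame(metric = colnames(tab),
                                             low = qs[1, ], high = qs[2, ],
                                             row.names = NULL))
    out$repeat_metrics <- as.data.frame(tab)
  }
  out
}

#' Evaluate on the held-out test portion (or an external set)
#'
#' Trains the final model on the whole cross-validation portion and
#' classifies the plan's test subjects, or an external feature matrix when
#' `external` is supplied.
#'
#' @inheritParams run_cv
#' @param external optional list `list(fm, labels)` replacing the held-out
#'   split as the evaluation set.
#' @return An `evaluation_report`.
#' @export
run_test <- function(fm, labels, plan, settings = src_settings(),
                     positive = sort(unique(as.character(labels)))[1],
                     external = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(plan, "split_plan"))
  labels <- as.character(labels)
  idx_of <- setNames(seq_len(nrow(fm$x)), fm$subject_id)
  tr_rows <- idx_of[as.character(plan$cv_ids)]
  classes <- c(positive, setdiff(sort(unique(labels)), positive))
  model <- src_fit(fm, labels, rows = tr_rows, settings = settings,
                   classes = classes, seed = plan$seed)
  if (is.null(external)) {
    te_rows <- idx_of[as.character(plan$test_ids)]
    pr <- src_predict(model, fm, rows = te_rows)
    truth <- labels[te_rows]
    what <- "independent test set"
  } else {
    pr <- src_predict(model, external$fm)
    truth <- as.character(external$labels)
    what <- "external validation set"
  }
  make_report(truth, pr$predicted, -pr$score, positive, settings, what)
}

#' Per-modality and combined metric table
#'
#' Runs the requested evaluation (pooled cross-validation or held-out test)
#' once per single modality and once on the concatenation of all of them,
#' and collects the diagnostic metrics into one table — the layout of the
#' study's per-sequence results tables (rows T1, T2, FLAIR, Combination).
#'
#' @param fm a multi-modality `feature_matrix`.
#' @param labels two-class vector per row.
#' @param plan a [make_split()] plan.
#' @param settings a [src_settings()] list.
#' @param positive positive class label.
#' @param mode `"cv"` or `"test"`.
#' @param repeats repeats for `mode = "cv"`.
#' @return Data frame with one row per sequence and columns accuracy,
#'   sensitivity, specificity, ppv, npv, auc.
#' @export
evaluate_modalities <- function(fm, labels, plan, settings = src_settings(),
                                positive = sort(unique(as.character(labels)))[1],
                                mode = c("cv", "test"), repeats = 1) {
  mode <- match.arg(mode)
  mods <- unique(fm$columns$modality)
  runs <- c(as.list(mods), list(mods))
  rows <- lapply(runs, function(mm) {
    fmm <- if (length(mm) == length(mods)) fm else subset_modalities(fm, mm)
    rep <- if (mode == "cv") {
      run_cv(fmm, labels, plan, settings, positive, repeats = repeats)
    } else {
      run_test(fmm, labels, plan, settings, positive)
    }
    data.frame(sequence = if (length(mm) == length(mods)) "Combination"
               else mm,
               t(rep$metrics), auc = rep$auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
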