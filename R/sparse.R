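#' Model settings for the sparse-representation classifier
#'
#' @param n_select number of features retained by screening (default 100).
#' @param max_atoms sparsity cap of the classification OMP solve (default 30,
#'   never more than the dictionary width).
#' @param tol residual-norm stopping tolerance of OMP.
#' @param gamma sparsity control constant of the l0-penalized objective;
#'   recorded as metadata (the greedy solver's operative knobs are
#'   `max_atoms` and `tol`).
#' @param screen_reps resampled repetitions used by feature screening.
#' @param screen_subsample fraction of training subjects drawn (without
#'   replacement, stratified) per screening repetition.
#' @param screen_max_atoms sparsity cap of each screening OMP solve. Kept
#'   well below the classification cap: once the class indicator is fit,
#'   deeper pursuits only accumulate noise atoms, so the union of supports
#'   over repetitions is sized commensurate with `n_select`.
#' @param normalize feature preparation for the dictionary: `"minmax"`
#'   (default) rescales each feature to `[0, 1]` using the training minimum
#'   and range, keeping all vectors in the nonnegative orthant — the
#'   geometry in which reconstruction from same-class columns is favored;
#'   `"zscore"` centers and scales instead.
#' @return A named settings list.
#' @export
src_settings <- function(n_select = 100, max_atoms = 30, tol = 1e-6,
                         gamma = 0.01, screen_reps = 10,
                         screen_subsample = 0.8, screen_max_atoms = 15,
                         normalize = c("minmax", "zscore")) {
  stopifnot(n_select >= 1, max_atoms >= 1, tol >= 0,
            screen_reps >= 1, screen_subsample > 0, screen_subsample <= 1)
  list(n_select = as.integer(n_select), max_atoms = as.integer(max_atoms),
       tol = tol, gamma = gamma, screen_reps = as.integer(screen_reps),
       screen_subsample = screen_subsample,
       screen_max_atoms = as.integer(screen_max_atoms),
       normalize = match.arg(normalize))
}

# vectorized column standard deviations (sample convention)
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

#' Per-feature normalizer
#'
#' Learns a per-feature affine transform `(x - center) / scale` on training
#' rows and applies it unchanged to test rows. `"zscore"` uses column mean
#' and standard deviation (floored at 1e-8, so constant columns transform to
#' zeros); `"minmax"` uses the column minimum and range, mapping training
#' values to `[0, 1]` — the nonnegative preparation the sparse dictionary
#' uses by default.
#'
#' @param x training matrix (rows = subjects).
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return A `normalizer`.
#' @export
fit_normalizer <- function(x, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 training rows to fit a normalizer")
  if (method == "zscore") {
    ctr <- colMeans(x)
    scl <- pmax(col_sds(x), 1e-8)
  } else {
    ctr <- apply(x, 2, min)
    scl <- pmax(apply(x, 2, max) - ctr, 1e-8)
  }
  structure(list(center = ctr, scale = scl, method = method),
            class = "normalizer")
}

#' @rdname fit_normalizer
#' @param nz a `normalizer`.
#' @export
apply_normalizer <- function(nz, x) {
  stopifnot(inherits(nz, "normalizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(nz$center)) {
    stop(sprintf("dimension mismatch: normalizer expects %d features, got %d",
                 length(nz$center), ncol(x)))
  }
  sweep(sweep(x, 2, nz$center, `-`), 2, nz$scale, `/`)
}

# scale matrix columns to unit Euclidean norm; zero columns stay zero
unit_columns <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- 1
  sweep(m, 2, nrm, `/`)
}

#' Orthogonal matching pursuit
#'
#' Greedy solver for the sparsity-penalized least-squares code: repeatedly
#' add the dictionary column most correlated with the current residual,
#' re-solve least squares on the active set, and stop at `max_atoms` atoms,
#' at residual norm `tol`, or when no column correlates with the residual.
#' A zero signal returns the all-zero code with residual 0.
#'
#' @param F dictionary, columns ideally unit-norm.
#' @param f signal vector, `length(f) == nrow(F)`.
#' @param max_atoms sparsity cap (default `min(30, ncol(F))`).
#' @param tol residual-norm stopping tolerance.
#' @param gamma sparsity-penalty constant carried as metadata.
#' @return Object of class `sparse_code`: `beta` (full-length coefficients,
#'   exact zeros off support), `support`, `residual_norm`, `gamma`,
#'   `max_atoms`.
#' @export
omp_solve <- function(F, f, max_atoms = min(30L, ncol(F)), tol = 1e-6,
                      gamma = 0.01) {
  F <- as.matrix(F)
  f <- as.numeric(f)
  if (nrow(F) != length(f)) {
    stop(sprintf("dimension mismatch: dictionary rows %d != signal length %d",
                 nrow(F), length(f)))
  }
  beta <- numeric(ncol(F))
  support <- integer(0)
  if (sqrt(sum(f^2)) == 0) {
    return(structure(list(beta = beta, support = support, residual_norm = 0,
                          gamma = gamma, max_atoms = max_atoms),
                     class = "sparse_code"))
  }
  r <- f
  b <- numeric(0)
  kmax <- min(max_atoms, ncol(F), nrow(F))
  for (it in seq_len(kmax)) {
    corr <- as.vector(crossprod(F, r))
    if (length(support)) corr[support] <- 0
    j <- which.max(abs(corr))
    if (abs(corr[j]) < 1e-12) break
    cand <- c(support, j)
    qrF <- qr(F[, cand, drop = FALSE])
    if (qrF$rank < length(cand)) break  # dependent atom: support is maximal
    support <- cand
    b <- qr.coef(qrF, f)
    r <- f - F[, support, drop = FALSE] %*% b
    if (sqrt(sum(r^2)) <= tol) break
  }
  beta[support] <- b
  structure(list(beta = beta, support = sort(support),
                 residual_norm = sqrt(sum(r^2)), gamma = gamma,
                 max_atoms = max_atoms),
            class = "sparse_code")
}

#' Sparse-coding feature screening
#'
#' Selects discriminative features by sparse-coding the class-indicator
#' vector (+1 for the first class, -1 for the second) against the transposed
#' training matrix: each feature is a dictionary column over subjects. Over
#' `screen_reps` stratified subsample repetitions the absolute OMP
#' coefficients are accumulated per feature; the top `k` by accumulated
#' magnitude are returned (ties, and any unfilled slots when fewer than `k`
#' features ever enter a support, are resolved by marginal absolute
#' correlation with the indicator, then by column index). Deterministic
#' given `seed`.
#'
#' @param x training matrix (subjects x features).
#' @param labels two-class factor/character vector, one per row.
#' @param k number of features to select.
#' @param settings a [src_settings()] list.
#' @param seed integer seed for the subsample draws.
#' @return Integer vector of `k` selected column indices, in rank order.
#' @export
screen_features <- function(x, labels, k = 100, settings = src_settings(),
                            seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (k < 1 || k > p) {
    stop(sprintf("k must be in 1..%d (number of features)", p))
  }
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2) stop("screening needs exactly two classes")
  y <- ifelse(as.character(labels) == cls[1], 1, -1)
  n <- nrow(x)
  score <- numeric(p)
  with_seed(seed, {
    for (rep in seq_len(settings$screen_reps)) {
      idx <- unlist(lapply(cls, function(cl) {
        rows <- which(as.character(labels) == cl)
        take <- max(2L, ceiling(settings$screen_subsample * length(rows)))
        rows[sample.int(length(rows), min(take, length(rows)))]
      }))
      xs <- x[idx, , drop = FALSE]
      ctr <- colMeans(xs)
      scl <- pmax(col_sds(xs), 1e-8)
      D <- unit_columns(sweep(sweep(xs, 2, ctr, `-`), 2, scl, `/`))
      code <- omp_solve(D, y[idx],
                        max_atoms = min(settings$screen_max_atoms,
                                        length(idx) - 1L, p),
                        tol = settings$tol)
      score <- score + abs(code$beta)
    }
  })
  # tie-break: marginal |correlation| with the indicator, then column index
  xc <- sweep(x, 2, colMeans(x), `-`)
  csd <- sqrt(colSums(xc^2))
  csd[csd == 0] <- 1
  marg <- abs(as.vector(crossprod(xc, y - mean(y)))) / csd
  ord <- order(-score, -marg, seq_len(p))
  ord[seq_len(k)]
}

#' Build the sparse-representation dictionary
#'
#' Arranges normalized training feature vectors as unit-norm columns of the
#' dictionary F (feature dimension x training subjects), class 1 columns
#' first, and stores the normalization state and selected feature set needed
#' to prepare test vectors identically.
#'
#' @param x training matrix (subjects x features), already imputed.
#' @param labels two-class vector per row; class order follows `classes`.
#' @param selected integer indices of screened features.
#' @param classes length-2 class label vector: `classes[1]` is class 1 (the
#'   tie-break winner), `classes[2]` class 2.
#' @param normalize normalizer method for the feature preparation (see
#'   [fit_normalizer()]); min-max by default so dictionary columns stay in
#'   the nonnegative orthant.
#' @return Object of class `sparse_dictionary`: `F`, `column_labels` (1/2),
#'   `classes`, `normalizer`, `selected`.
#' @export
sparse_dictionary <- function(x, labels, selected,
                              classes = sort(unique(as.character(labels))),
                              normalize = "minmax") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(length(classes) == 2, all(labels %in% classes))
  m <- sum(labels == classes[1])
  n <- sum(labels == classes[2])
  if (m < 1 || n < 1) stop("each class needs at least one training sample")
  nz <- fit_normalizer(x, method = normalize)
  xn <- apply_normalizer(nz, x)[, selected, drop = FALSE]
  ord <- order(match(labels, classes))
  F <- unit_columns(t(xn[ord, , drop = FALSE]))
  dimnames(F) <- NULL
  structure(list(F = F, column_labels = match(labels, classes)[ord],
                 classes = classes, normalizer = nz, selected = selected,
                 m = m, n = n),
            class = "sparse_dictionary")
}

#' Classify a prepared test vector by minimum class residual
#'
#' Sparse-codes `f` against the dictionary, then reconstructs it per class
#' using only that class's coefficients and predicts the class with the
#' smaller Euclidean reconstruction residual (exact ties go to class 1). The
#' continuous decision score is `(r1 - r2) / (r1 + r2 + 1e-12)`: positive
#' means class 2.
#'
#' @param dict a [sparse_dictionary()].
#' @param f numeric vector already normalized with the dictionary's
#'   normalizer and restricted to the selected features (see
#'   [src_predict()] for the end-to-end path).
#' @param max_atoms,tol OMP controls.
#' @return Object of class `class_decision`: `residuals` (length 2),
#'   `predicted` (class label), `score`, `code`.
#' @export
classify <- function(dict, f, max_atoms = min(30L, ncol(dict$F)),
                     tol = 1e-6) {
  stopifnot(inherits(dict, "sparse_dictionary"))
  f <- as.numeric(f)
  if (length(f) != nrow(dict$F)) {
    stop(sprintf("dimension mismatch: expected %d features, got %d",
                 nrow(dict$F), length(f)))
  }
  code <- omp_solve(dict$F, f, max_atoms = max_atoms, tol = tol)
  res <- vapply(1:2, function(cl) {
    bc <- code$beta
    bc[dict$column_labels != cl] <- 0
    sqrt(sum((f - dict$F %*% bc)^2))
  }, numeric(1))
  predicted <- dict$classes[if (res[2] < res[1]) 2L else 1L]
  score <- (res[1] - res[2]) / (res[1] + res[2] + 1e-12)
  structure(list(residuals = setNames(res, dict$classes),
                 predicted = predicted, score = score, code = code),
            class = "class_decision")
}

#' Fit the full sparse-representation model on a training partition
#'
#' Pipeline order inside the partition: impute flagged cells from training
#' medians, screen features by sparse coding, then build the residual
#' classifier's dictionary. Nothing is learned from rows outside `rows`.
#'
#' @param fm a `feature_matrix`.
#' @param labels two-class vector, one entry per `fm` row.
#' @param rows training row indices.
#' @param settings a [src_settings()] list.
#' @param classes class order (class 1 first); default sorted labels.
#' @param seed seed for the screening subsamples.
#' @return Object of class `src_model`.
#' @export
src_fit <- function(fm, labels, rows = seq_len(nrow(fm$x)),
                    settings = src_settings(),
                    classes = sort(unique(as.character(labels[rows]))),
                    seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- as.character(labels)
  if (length(unique(labels[rows])) != 2) {
    stop("training partition must contain both classes")
  }
  imp <- fit_imputer(fm, rows)
  xtr <- apply_imputer(imp, fm$x[rows, , drop = FALSE],
                       fm$flags[rows, , drop = FALSE])
  k <- min(settings$n_select, ncol(xtr))
  sel <- screen_features(xtr, labels[rows], k = k, settings = settings,
                         seed = seed)
  dict <- sparse_dictionary(xtr, labels[rows], sel, classes = classes,
                            normalize = settings$normalize %||% "minmax")
  structure(list(dictionary = dict, imputer = imp, settings = settings,
                 classes = classes, seed = seed),
            class = "src_model")
}

#' Predict with a fitted sparse-representation model
#'
#' Test rows follow exactly the training preparation: training-median
#' imputation, training normalizer, screened feature subset, unit-norm
#' scaling, then minimum-class-residual classification.
#'
#' @param model an [src_fit()] result.
#' @param fm a `feature_matrix` holding the rows to classify.
#' @param rows row indices to classify; default all.
#' @return Data frame with `subject_id`, `predicted`, residuals `r1`/`r2`
#'   and `score` (positive means class 2 of the model's class order).
#' @export
src_predict <- function(model, fm, rows = seq_len(nrow(fm$x))) {
  stopifnot(inherits(model, "src_model"), inherits(fm, "feature_matrix"))
  dict <- model$dictionary
  x <- apply_imputer(model$imputer, fm$x[rows, , drop = FALSE],
                     fm$flags[rows, , drop = FALSE])
  xn <- apply_normalizer(dict$normalizer, x)[, dict$selected, drop = FALSE]
  out <- lapply(seq_len(nrow(xn)), function(i) {
    f <- xn[i, ]
    nf <- sqrt(sum(f^2))
    if (nf > 0) f <- f / nf
    d <- classify(dict, f, max_atoms = min(model$settings$max_atoms,
                                           ncol(dict$F)),
                  tol = model$settings$tol)
    data.frame(predicted = d$predicted, r1 = d$residuals[1],
               r2 = d$residuals[2], score = d$score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- data.frame(subject_id = fm$subject_id[rows], res,
                    row.names = NULL, stringsAsFactors = FALSE)
  res
}

#' Serialize / restore a fitted model as a plain-text bundle
#'
#' Writes the dictionary matrix as CSV, the column class labels, the
#' normalizer and imputer state, the selected feature names and the settings
#' as JSON into a directory; `load_src_model()` restores an equivalent
#' model.
#'
#' @param model an [src_fit()] result.
#' @param dir bundle directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_src_model <- function(model, dir) {
  stopifnot(inherits(model, "src_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- model$dictionary
  write.csv(d$F, file.path(dir, "dictionary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(column_labels = d$column_labels, classes = d$classes,
         selected = d$selected, m = d$m, n = d$n,
         normalizer = list(center = unname(d$normalizer$center),
                           scale = unname(d$normalizer$scale),
                           names = names(d$normalizer$center),
                           method = d$normalizer$method),
         imputer_medians = as.list(model$imputer$medians),
         settings = model$settings, seed = model$seed),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_src_model
#' @export
load_src_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  F <- as.matrix(read.csv(file.path(dir, "dictionary.csv")))
  dimnames(F) <- NULL
  nz <- structure(list(center = setNames(meta$normalizer$center,
                                         meta$normalizer$names),
                       scale = setNames(meta$normalizer$scale,
                                        meta$normalizer$names),
                       method = meta$normalizer$method),
                  class = "normalizer")
  dict <- structure(list(F = F, column_labels = meta$column_labels,
                         classes = meta$classes, normalizer = nz,
                         selected = meta$selected, m = meta$m, n = meta$n),
                    class = "sparse_dictionary")
  imp <- structure(list(medians = unlist(meta$imputer_medians)),
                   class = "imputer")
  structure(list(dictionary = dict, imputer = imp,
                 settings = meta$settings, classes = meta$classes,
                 seed = meta$seed),
            class = "src_model")
}
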