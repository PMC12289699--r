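test_that("the z-score normalizer satisfies its identities", {
  set.seed(2)
  x <- matrix(rnorm(60, 5, 3), 12, 5)
  x[, 3] <- 7  # constant column
  nz <- fit_normalizer(x)
  xn <- apply_normalizer(nz, x)
  expect_equal(unname(colMeans(xn)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(xn[, -3], 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(xn[, 3]), rep(0, 12))            # floored scale
  expect_equal(apply_normalizer(nz, x[4, , drop = FALSE]),
               xn[4, , drop = FALSE])                  # train/test identical
  expect_error(fit_normalizer(x[1, , drop = FALSE]), ">= 2 training rows")
  expect_error(apply_normalizer(nz, x[, 1:3]), "dimension mismatch")
})

test_that("the min-max normalizer maps training columns onto [0, 1]", {
  set.seed(3)
  x <- matrix(rnorm(40), 8, 5)
  nz <- fit_normalizer(x, method = "minmax")
  xn <- apply_normalizer(nz, x)
  expect_equal(unname(apply(xn, 2, min)), rep(0, 5))
  expect_equal(unname(apply(xn, 2, max)), rep(1, 5))
})

test_that("OMP recovers trivial and exactly sparse codes", {
  F <- diag(8)
  code <- omp_solve(F, 3 * F[, 5])
  expect_identical(code$support, 5L)
  expect_equal(code$beta[5], 3)
  expect_equal(code$residual_norm, 0, tolerance = 1e-12)
  expect_true(all(code$beta[-5] == 0))       # exact zeros off support

  set.seed(7)
  G <- matrix(rnorm(80), 20, 4)
  G <- sweep(G, 2, sqrt(colSums(G^2)), `/`)
  code2 <- omp_solve(G, G[, 2])
  expect_identical(code2$support, 2L)
  expect_lt(code2$residual_norm, 1e-10)

  z <- omp_solve(G, rep(0, 20))
  expect_equal(z$beta, rep(0, 4))
  expect_equal(z$residual_norm, 0)
  expect_error(omp_solve(G, rep(1, 3)), "dimension mismatch")
})

test_that("OMP support equals exhaustive subset search on noiseless problems", {
  # greedy pursuit is not guaranteed to recover on highly coherent random
  # dictionaries; the testable property is that every exact (zero-residual)
  # pursuit finds the same support as exhaustive search, and that recovery
  # succeeds on the overwhelming majority of Gaussian instances
  recovered <- 0
  for (seed in 1:10) {
    set.seed(seed)
    F <- matrix(rnorm(200), 20, 10)
    F <- sweep(F, 2, sqrt(colSums(F^2)), `/`)
    truth <- sort(sample(10, 3))
    f <- as.vector(F[, truth] %*% runif(3, 1, 3))
    code <- omp_solve(F, f, max_atoms = 3)
    expect_lte(length(code$support), 3)
    if (code$residual_norm < 1e-8) {
      recovered <- recovered + 1
      oracle <- oracle_best_subset(F, f, 3)
      expect_identical(code$support, as.integer(oracle$support))
    }
  }
  expect_gte(recovered, 8)
})

test_that("screening finds planted informative features", {
  set.seed(15)
  n <- 60
  y <- rep(c("A", "B"), each = n / 2)
  hits <- 0
  for (rep in 1:10) {
    x <- matrix(rnorm(n * 52), n)
    x[y == "B", 7] <- x[y == "B", 7] + 3
    x[y == "B", 31] <- x[y == "B", 31] - 3
    sel <- sort(screen_features(x, y, k = 2, seed = rep))
    oracle <- oracle_best_pair(x, ifelse(y == "A", 1, -1))
    expect_identical(oracle, c(7L, 31L))   # sanity: LS oracle agrees
    if (identical(sel, c(7L, 31L))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("screening degenerates gracefully: identity selection and errors", {
  set.seed(16)
  x <- matrix(rnorm(20 * 6), 20)
  y <- rep(c("A", "B"), each = 10)
  expect_setequal(screen_features(x, y, k = 6, seed = 1), 1:6)
  expect_error(screen_features(x, y, k = 7, seed = 1), "k must be in 1..6")
})

test_that("screening under permuted labels picks planted features at chance", {
  set.seed(17)
  n <- 60
  x <- matrix(rnorm(n * 52), n)
  y <- rep(c("A", "B"), each = n / 2)
  x[y == "B", 7] <- x[y == "B", 7] + 3
  x[y == "B", 31] <- x[y == "B", 31] - 3
  overlap <- vapply(1:20, function(r) {
    set.seed(100 + r)
    yp <- sample(y)
    length(intersect(screen_features(x, yp, k = 2, seed = r), c(7L, 31L)))
  }, numeric(1))
  # chance overlap of a 2-of-52 draw with a fixed pair: E = 2*2/52 ~ 0.077
  expect_lt(mean(overlap), 0.5)
})

test_that("class residuals identify duplicated training columns and break ties low", {
  set.seed(21)
  x <- matrix(rnorm(12 * 20, 10, 2), 12)
  y <- rep(c("A", "B"), each = 6)
  dict <- sparse_dictionary(x, y, selected = 1:20)
  # a test vector equal to a class-1 (A) training column reconstructs itself
  f <- dict$F[, 2]
  d <- classify(dict, f)
  expect_lt(d$residuals[1], 1e-8)
  expect_equal(d$predicted, "A")
  expect_lte(d$residuals[1], d$residuals[2])

  # zero vector: both residuals 0, tie goes to class 1 with score 0
  d0 <- classify(dict, rep(0, nrow(dict$F)))
  expect_equal(unname(d0$residuals), c(0, 0))
  expect_equal(d0$predicted, "A")
  expect_equal(d0$score, 0)
  expect_error(classify(dict, rep(0, 3)), "dimension mismatch")
})

test_that("the joint sparse code never reconstructs worse than the zero code", {
  # the class-restricted residuals of the minimum-residual rule carry no
  # such bound (opposite-class parts of the joint code can cancel), but the
  # joint OMP residual can never exceed ||f|| because least squares on any
  # support dominates the zero coefficient vector
  set.seed(22)
  x <- matrix(rnorm(16 * 30), 16)
  y <- rep(c("A", "B"), each = 8)
  dict <- sparse_dictionary(x, y, selected = 1:30)
  for (i in 1:10) {
    f <- rnorm(30)
    d <- classify(dict, f)
    expect_lte(d$code$residual_norm, sqrt(sum(f^2)) + 1e-10)
    expect_true(all(d$residuals >= 0))
    expect_equal(d$predicted,
                 dict$classes[which.min(d$residuals)])
  }
})

test_that("SRC matches a nearest-subspace oracle on well-separated classes", {
  set.seed(23)
  # feature dimension must exceed the per-class column count, else both
  # class subspaces are complete and the nearest-subspace oracle is vacuous
  n_tr <- 30; n_te <- 20; p <- 80
  # disjoint activation patterns: class A high on the first half of the
  # features, class B on the second half
  make_class <- function(n, cls) {
    m <- matrix(rnorm(n * p), n)
    cols <- if (cls == "A") 1:(p / 2) else (p / 2 + 1):p
    m[, cols] <- m[, cols] + 4
    m
  }
  xtr <- rbind(make_class(n_tr, "A"), make_class(n_tr, "B"))
  xte <- rbind(make_class(n_te / 2, "A"), make_class(n_te / 2, "B"))
  ytr <- rep(c("A", "B"), each = n_tr)
  yte <- rep(c("A", "B"), each = n_te / 2)
  dict <- sparse_dictionary(xtr, ytr, selected = 1:p)
  xn <- apply_normalizer(dict$normalizer, xte)
  pred <- oracle_pred <- character(n_te)
  for (i in 1:n_te) {
    f <- xn[i, ] / sqrt(sum(xn[i, ]^2))
    pred[i] <- classify(dict, f)$predicted
    # oracle: full class-restricted least squares (nearest subspace)
    r <- vapply(c("A", "B"), function(cl) {
      Fc <- dict$F[, dict$classes[dict$column_labels] == cl, drop = FALSE]
      sqrt(sum(qr.resid(qr(Fc), f)^2))
    }, numeric(1))
    oracle_pred[i] <- names(which.min(r))
  }
  expect_lte(sum((pred == yte) != (oracle_pred == yte)), 1)
  expect_gte(mean(pred == yte), 0.95)
})

test_that("a model bundle roundtrips through disk", {
  fm <- tiny_feature_matrix()
  task <- task_labels(fm$group, "CI_vs_HC")
  model <- src_fit(fm, task$labels, settings = src_settings(n_select = 40),
                   classes = c("CI", "HC"), seed = 3)
  dir <- withr::local_tempdir()
  save_src_model(model, dir)
  back <- load_src_model(dir)
  expect_equal(back$dictionary$F, model$dictionary$F, tolerance = 1e-12)
  p1 <- src_predict(model, fm)
  p2 <- src_predict(back, fm)
  expect_identical(p1$predicted, p2$predicted)
  expect_equal(p1$score, p2$score, tolerance = 1e-10)
})

test_that("nonnegative dictionary preparation rescues mean-shift geometry", {
  # after symmetric z-centering the two classes sit on anti-parallel rays
  # and the unsigned residual rule cannot separate them; min-max keeps the
  # vectors in the nonnegative orthant where same-class reconstruction wins
  set.seed(60)
  n1 <- 40; n2 <- 20; p <- 60
  x <- matrix(rnorm((n1 + n2) * p), n1 + n2)
  x[1:n1, 1:20] <- x[1:n1, 1:20] + 4
  x[(n1 + 1):(n1 + n2), 21:40] <- x[(n1 + 1):(n1 + n2), 21:40] + 4
  labels <- c(rep("CI", n1), rep("HC", n2))
  fm <- fake_feature_matrix(x, c(rep("MCI", n1), rep("HC", n2)))
  plan <- make_split(labels, n_folds = 5, seed = 1, ids = fm$subject_id)
  acc <- sapply(c("zscore", "minmax"), function(nm) {
    unname(run_cv(fm, labels, plan,
                  src_settings(n_select = 20, normalize = nm),
                  positive = "CI")$metrics["accuracy"])
  })
  expect_gte(acc[["minmax"]], 0.95)
  expect_gt(acc[["minmax"]], acc[["zscore"]] + 0.2)
})
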