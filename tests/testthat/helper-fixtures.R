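# Shared tiny fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

tiny_spec <- function(n_per_group = 4, n_regions = 5, seed = 101, ...) {
  cohort_spec(n_per_group = n_per_group, grid_shape = c(28, 28, 14),
              n_regions = n_regions, seed = seed, ...)
}

# a small 3-group, 3-modality cohort reused by pipeline tests
tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(tiny_spec())
  }
  .fixture_env$cohort
}

tiny_feature_matrix <- function() {
  if (is.null(.fixture_env$fm)) {
    .fixture_env$fm <- build_feature_matrix(tiny_cohort())
  }
  .fixture_env$fm
}

# random masked level array for oracle-equivalence checks
random_small_region <- function(seed, max_dim = 3, n_levels = 3) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  lev <- array(sample(0:n_levels, prod(d), replace = TRUE,
                      prob = c(0.25, rep(0.75 / n_levels, n_levels))), d)
  if (all(lev == 0)) lev[1, 1, 1] <- 1L
  lev
}

# a feature_matrix built directly from a numeric matrix, bypassing imaging
fake_feature_matrix <- function(x, groups) {
  colnames(x) <- sprintf("T1|r01|f%03d", seq_len(ncol(x)))
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  structure(list(
    x = x,
    flags = matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x)),
    subject_id = rownames(x),
    group = groups,
    columns = data.frame(modality = "T1", region = 1L,
                         feature = sprintf("f%03d", seq_len(ncol(x))),
                         name = colnames(x), stringsAsFactors = FALSE),
    settings = list(n_levels = NA, min_voxels = NA, modalities = "T1")),
    class = "feature_matrix")
}
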