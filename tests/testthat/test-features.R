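test_that("intensity statistics have their closed-form values", {
  vol <- array(c(1, 2, 3, 4, 5), c(5, 1, 1))
  lm <- array(1L, c(5, 1, 1))
  fi <- intensity_features(quantize_region(vol, lm, 1L, n_levels = 5))
  v <- fi$values
  expect_equal(unname(v["int_mean"]), 3)
  expect_equal(unname(v["int_median"]), 3)
  expect_equal(unname(v["int_range"]), 4)
  expect_equal(unname(v["int_variance"]), 2)      # population convention
  expect_equal(unname(v["int_sd"]), sqrt(2))
  expect_equal(unname(v["int_energy"]), 55)
  expect_equal(unname(v["int_rms"]), sqrt(11))
  expect_equal(unname(v["int_mad"]), 6 / 5)
  expect_equal(unname(v["int_min"]), 1)
  expect_equal(unname(v["int_max"]), 5)
  # one value per level: uniform histogram
  expect_equal(unname(v["int_h_uniformity"]), 5 * (1 / 5)^2)
  expect_equal(unname(v["int_h_mean"]), 3)
})

test_that("constant regions hit the documented degenerate limits", {
  vol <- array(7.7, c(3, 3, 2))
  lm <- array(1L, c(3, 3, 2))
  q <- quantize_region(vol, lm, 1L, 32)
  fi <- intensity_features(q)
  expect_equal(unname(fi$values["int_sd"]), 0)
  expect_equal(unname(fi$values["int_h_uniformity"]), 1)
  expect_equal(unname(fi$values["int_skewness"]), 0)
  expect_equal(unname(fi$values["int_kurtosis"]), 0)
  expect_true(all(fi$flags[c("int_skewness", "int_kurtosis")]))

  ft <- texture_features(build_matrices(q))
  expect_equal(unname(ft$values["glcm_contrast"]), 0)
  expect_equal(unname(ft$values["glcm_energy"]), 1)
  expect_equal(unname(ft$values["glcm_dissimilarity"]), 0)
  expect_equal(unname(ft$values["glcm_correlation"]), 0)
  expect_true(ft$flags["glcm_correlation"])
})

test_that("moment conventions match a direct Monte-Carlo at large n", {
  # pinned convention: population moments, non-excess kurtosis
  set.seed(4)
  n <- 1e5
  x <- rnorm(n)
  vol <- array(x, c(100, 100, 10))
  fi <- intensity_features(quantize_region(vol, array(1L, c(100, 100, 10)),
                                           1L, 32))
  expect_lt(abs(fi$values["int_skewness"]), 4 * sqrt(6 / n))
  expect_lt(abs(fi$values["int_kurtosis"] - 3), 4 * sqrt(24 / n))
})

test_that("texture features equal direct summation over the enumerated matrices", {
  vol <- array(c(0, 0, 1, 1), c(2, 2, 1))
  lm <- array(1L, c(2, 2, 1))
  m <- build_matrices(quantize_region(vol, lm, 1L, n_levels = 2))
  got <- texture_features(m)$values

  # independent evaluation from the frozen hand counts
  P <- matrix(c(2, 4, 4, 2), 2, 2) / 12
  i <- row(P); j <- col(P)
  px <- rowSums(P); mu <- sum(1:2 * px); s2 <- sum(((1:2) - mu)^2 * px)
  expect_equal(unname(got["glcm_energy"]), sum(P^2))
  expect_equal(unname(got["glcm_contrast"]), sum((i - j)^2 * P))
  expect_equal(unname(got["glcm_correlation"]),
               (sum(i * j * P) - mu^2) / s2)
  expect_equal(unname(got["glcm_homogeneity"]), sum(P / (1 + abs(i - j))))
  expect_equal(unname(got["glcm_variance"]), sum((i - mu)^2 * P))
  expect_equal(unname(got["glcm_sum_average"]), sum((i + j) * P))
  expect_equal(unname(got["glcm_entropy"]), -sum(P * log2(P)))
  expect_equal(unname(got["glcm_dissimilarity"]), sum(abs(i - j) * P))

  R <- rbind(c(24, 1), c(24, 1)); Nr <- 50; Np <- 4
  ir <- row(R); jr <- col(R)
  expect_equal(unname(got["glrlm_sre"]), sum(R / jr^2) / Nr)
  expect_equal(unname(got["glrlm_lre"]), sum(R * jr^2) / Nr)
  expect_equal(unname(got["glrlm_gln"]), (25^2 + 25^2) / Nr)
  expect_equal(unname(got["glrlm_rln"]), (48^2 + 2^2) / Nr)
  expect_equal(unname(got["glrlm_rp"]), 50 / (13 * 4))
  expect_equal(unname(got["glrlm_lgre"]), sum(R / ir^2) / Nr)
  expect_equal(unname(got["glrlm_hgre"]), sum(R * ir^2) / Nr)
  expect_equal(unname(got["glrlm_srlge"]), sum(R / (ir^2 * jr^2)) / Nr)
  expect_equal(unname(got["glrlm_srhge"]), sum(R * ir^2 / jr^2) / Nr)
  expect_equal(unname(got["glrlm_lrlge"]), sum(R * jr^2 / ir^2) / Nr)
  expect_equal(unname(got["glrlm_lrhge"]), sum(R * ir^2 * jr^2) / Nr)
  pr <- R / Nr
  expect_equal(unname(got["glrlm_glv"]),
               sum((ir - sum(ir * pr))^2 * pr))
  expect_equal(unname(got["glrlm_rlv"]),
               sum((jr - sum(jr * pr))^2 * pr))

  Z <- rbind(c(0, 1), c(0, 1)); Nz <- 2
  iz <- row(Z); jz <- col(Z)
  expect_equal(unname(got["glszm_sze"]), sum(Z / jz^2) / Nz)
  expect_equal(unname(got["glszm_lze"]), sum(Z * jz^2) / Nz)
  expect_equal(unname(got["glszm_gln"]), (1 + 1) / Nz)
  expect_equal(unname(got["glszm_zsn"]), (0 + 4) / Nz)
  expect_equal(unname(got["glszm_zp"]), 2 / 4)
  expect_equal(unname(got["glszm_lzhge"]), sum(Z * iz^2 * jz^2) / Nz)
  pz <- Z / Nz
  expect_equal(unname(got["glszm_glv"]),
               sum((iz - sum(iz * pz))^2 * pz))
  expect_equal(unname(got["glszm_zsv"]),
               sum((jz - sum(jz * pz))^2 * pz))

  # NGTDM from n = (2,2), s = (4/3, 4/3)
  p <- c(0.5, 0.5); s <- c(4 / 3, 4 / 3); lv <- 1:2; ntot <- 4
  eps <- 1e-6
  expect_equal(unname(got["ngtdm_coarseness"]), 1 / (eps + sum(p * s)))
  expect_equal(unname(got["ngtdm_contrast"]),
               sum(outer(p, p) * outer(lv, lv, function(a, b) (a - b)^2)) /
                 (2 * 1) * sum(s) / ntot)
  expect_equal(unname(got["ngtdm_busyness"]),
               sum(p * s) / (eps + sum(abs(outer(lv * p, lv * p, `-`)))))
  ps <- p * s
  expect_equal(unname(got["ngtdm_complexity"]),
               sum(abs(outer(lv, lv, `-`)) * outer(ps, ps, `+`) /
                     (ntot * outer(p, p, `+`))))
  expect_equal(unname(got["ngtdm_strength"]),
               sum(outer(p, p, `+`) *
                     outer(lv, lv, function(a, b) (a - b)^2)) /
                 (eps + sum(s)))
})

test_that("an alternating two-level stripe attains the maximal GLCM contrast", {
  # brute-force oracle over symmetric 2x2 normalized GLCMs with equal
  # marginals: P = [[0.5-a, a], [a, 0.5-a]], contrast = 2a, maximal at
  # a = 0.5
  a <- seq(0, 0.5, by = 0.001)
  max_contrast <- max(2 * a)
  vol <- array(rep(c(0, 1), 8), c(16, 1, 1))
  lm <- array(1L, c(16, 1, 1))
  ft <- texture_features(build_matrices(quantize_region(vol, lm, 1L, 2)))
  expect_equal(unname(ft$values["glcm_contrast"]), max_contrast)
})

test_that("the full region vector is 57 long, ordered, deterministic and scale-free", {
  set.seed(30)
  vol <- array(rnorm(480, 100, 5), c(8, 12, 5))
  lm <- array(0L, c(8, 12, 5))
  lm[2:7, 2:11, 2:4] <- 1L
  f1 <- extract_region_features(vol, lm, 1L, "T1")
  expect_length(f1$values, 57)
  cat57 <- feature_catalogue()
  expect_identical(names(f1$values), cat57$name)
  expect_equal(nrow(cat57), 57)
  expect_equal(sum(cat57$category == "intensity"), 18)
  expect_equal(sum(cat57$category != "intensity"), 39)

  f2 <- extract_region_features(vol, lm, 1L, "T1")
  expect_identical(f1$values, f2$values)

  # quantized-domain features invariant under positive affine rescaling
  f3 <- extract_region_features(2.5 * vol + 40, lm, 1L, "T1")
  quantized <- cat57$name[cat57$category != "intensity" |
                            startsWith(cat57$name, "int_h_")]
  expect_equal(f1$values[quantized], f3$values[quantized],
               tolerance = 1e-10)
})

test_that("tiny regions are flagged wholesale for downstream imputation", {
  vol <- array(rnorm(8), c(2, 2, 2))
  lm <- array(1L, c(2, 2, 2))
  f <- extract_region_features(vol, lm, 1L, "T1", min_voxels = 10)
  expect_true(all(f$flags))
  expect_true(all(is.finite(f$values)))
})

test_that("smoother textures have lower expected GLCM contrast", {
  contrast_at <- function(sig) {
    eff <- group_effect(mean_shift = c(HC = 0), smoothness = c(HC = sig),
                        noise_sd = c(HC = 1), modality_gain = c(T1 = 1))
    spec <- cohort_spec(n_per_group = 3, n_regions = 2,
                        grid_shape = c(20, 20, 10), seed = 50,
                        group_labels = "HC", modalities = "T1", effect = eff)
    lm <- generate_label_map(spec)
    mean(vapply(1:3, function(i) {
      s <- generate_subject(spec, "HC", i, label_map = lm)
      unname(extract_region_features(s$volumes$T1, lm, 1L,
                                     "T1")$values["glcm_contrast"])
    }, numeric(1)))
  }
  c0 <- contrast_at(0)
  c1 <- contrast_at(1)
  c2 <- contrast_at(2)
  expect_gt(c0, c1)
  expect_gt(c1, c2)
})
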