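#' The 57-feature radiomic catalogue
#'
#' Fixed, ordered catalogue of the features computed per (region, modality):
#' 18 intensity features (12 on native intensities, 6 `h-` features on the
#' normalized quantized histogram), then 8 GLCM, 13 GLRLM, 13 GLSZM and 5
#' NGTDM texture features.
#'
#' @return Data frame with columns `name` (machine id), `display` (human
#'   label) and `category`.
#' @export
feature_catalogue <- function() {
  rbind(
    data.frame(category = "intensity", name = c(
      "int_energy", "int_h_energy", "int_kurtosis", "int_max", "int_mad",
      "int_mean", "int_median", "int_min", "int_range", "int_rms",
      "int_skewness", "int_sd", "int_h_uniformity", "int_variance",
      "int_h_mean", "int_h_variance", "int_h_skewness", "int_h_kurtosis"),
      display = c(
        "Energy", "h-Energy", "Kurtosis", "Max", "Mean absolute deviation",
        "Mean", "Median", "Min", "Range", "Root mean square", "Skewness",
        "Standard-deviation", "h-Uniformity", "Variance", "h-Mean",
        "h-Variance", "h-Skewness", "h-Kurtosis")),
    data.frame(category = "glcm", name = c(
      "glcm_energy", "glcm_contrast", "glcm_correlation", "glcm_homogeneity",
      "glcm_variance", "glcm_sum_average", "glcm_entropy",
      "glcm_dissimilarity"),
      display = c("Energy", "Contrast", "Correlation", "Homogeneity",
                  "Variance", "Sum average", "Entropy", "Dissimilarity")),
    data.frame(category = "glrlm", name = c(
      "glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_rp",
      "glrlm_lgre", "glrlm_hgre", "glrlm_srlge", "glrlm_srhge",
      "glrlm_lrlge", "glrlm_lrhge", "glrlm_glv", "glrlm_rlv"),
      display = c("Short run emphasis", "Long run emphasis",
                  "Gray-level nonuniformity", "Run-length nonuniformity",
                  "Run percentage", "Low gray-level run emphasis",
                  "High gray-level run emphasis",
                  "Short run low gray-level emphasis",
                  "Short run high gray-level emphasis",
                  "Long run low gray-level emphasis",
                  "Long run high gray-level emphasis",
                  "Gray-level variance", "Run-length variance")),
    data.frame(category = "glszm", name = c(
      "glszm_sze", "glszm_lze", "glszm_gln", "glszm_zsn", "glszm_zp",
      "glszm_lgze", "glszm_hgze", "glszm_szlge", "glszm_szhge",
      "glszm_lzlge", "glszm_lzhge", "glszm_glv", "glszm_zsv"),
      display = c("Small zone emphasis", "Large zone emphasis",
                  "Gray-level nonuniformity", "Zone-size nonuniformity",
                  "Zone percentage", "Low gray-level zone emphasis",
                  "High gray-level zone emphasis",
                  "Small zone low gray-level emphasis",
                  "Small zone high gray-level emphasis",
                  "Large zone low gray-level emphasis",
                  "Large zone high gray-level emphasis",
                  "Gray-level variance", "Zone-size variance")),
    data.frame(category = "ngtdm", name = c(
      "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
      "ngtdm_complexity", "ngtdm_strength"),
      display = c("Coarseness", "Contrast", "Busyness", "Complexity",
                  "Strength"))
  )
}

# small guard used by several denominators in the NGTDM features
.ngtdm_eps <- 1e-6

#' Intensity features of a quantized region
#'
#' Twelve statistics on the native voxel intensities (population variance
#' convention, non-excess kurtosis) and six `h-` statistics on the
#' normalized quantized-level histogram: `h-Mean`, `h-Variance`,
#' `h-Skewness`, `h-Kurtosis` are the moments of the level distribution,
#' `h-Uniformity` is `sum(p^2)` and `h-Energy` is the second raw moment
#' `sum(p * level^2)`. Degenerate moments of a constant region (skewness,
#' kurtosis and their histogram analogues) are substituted by 0 and flagged.
#'
#' @param q a [quantize_region()] result.
#' @return List with `values` (18 named scalars in catalogue order) and
#'   `flags` (logical, TRUE where a degenerate substitution was applied).
#' @export
intensity_features <- function(q) {
  stopifnot(inherits(q, "quantized_region"))
  x <- q$voxel_values
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  flags <- setNames(rep(FALSE, 18),
                    feature_catalogue()$name[1:18])
  skew <- kurt <- 0
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  } else {
    flags[c("int_skewness", "int_kurtosis")] <- TRUE
  }
  lev <- q$quantized_map[q$quantized_map > 0L]
  p <- tabulate(lev, nbins = q$n_levels) / n
  lv <- seq_len(q$n_levels)
  h_mu <- sum(lv * p)
  h_m2 <- sum((lv - h_mu)^2 * p)
  h_skew <- h_kurt <- 0
  if (h_m2 > 0) {
    h_skew <- sum((lv - h_mu)^3 * p) / h_m2^1.5
    h_kurt <- sum((lv - h_mu)^4 * p) / h_m2^2
  } else {
    flags[c("int_h_skewness", "int_h_kurtosis")] <- TRUE
  }
  values <- c(
    int_energy = sum(x^2),
    int_h_energy = sum(p * lv^2),
    int_kurtosis = kurt,
    int_max = max(x),
    int_mad = mean(abs(x - mu)),
    int_mean = mu,
    int_median = median(x),
    int_min = min(x),
    int_range = max(x) - min(x),
    int_rms = sqrt(mean(x^2)),
    int_skewness = skew,
    int_sd = sqrt(m2),
    int_h_uniformity = sum(p^2),
    int_variance = m2,
    int_h_mean = h_mu,
    int_h_variance = h_m2,
    int_h_skewness = h_skew,
    int_h_kurtosis = h_kurt)
  list(values = values, flags = flags)
}

#' Texture features from the four count structures
#'
#' Computes 8 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM features from
#' [build_matrices()] output. Counts are aggregated over directions before
#' normalization (merged strategy); run percentage is normalized by the
#' number of directions times the voxel count so it stays in (0, 1]. A
#' zero-variance GLCM yields Correlation 0 (flagged); NGTDM denominators are
#' guarded by a 1e-6 epsilon; a single-voxel region yields the documented
#' constant-image limits, all flagged.
#'
#' @param m a [build_matrices()] result.
#' @return List with `values` (39 named scalars in catalogue order) and
#'   `flags`.
#' @export
texture_features <- function(m) {
  stopifnot(inherits(m, "texture_matrices"))
  cat57 <- feature_catalogue()
  tex_names <- cat57$name[cat57$category != "intensity"]
  flags <- setNames(rep(FALSE, length(tex_names)), tex_names)
  vals <- setNames(numeric(length(tex_names)), tex_names)

  ## ---- GLCM (Haralick, on the normalized symmetric matrix) ----
  P <- m$glcm_norm
  L <- m$n_levels
  if (sum(P) <= 0) {
    # single-voxel region: constant-image limits
    vals["glcm_energy"] <- 1
    vals["glcm_homogeneity"] <- 1
    vals["glcm_sum_average"] <- 2
    flags[startsWith(names(flags), "glcm_")] <- TRUE
  } else {
    I <- row(P)
    J <- col(P)
    px <- rowSums(P)
    mu <- sum(seq_len(L) * px)
    var_m <- sum((seq_len(L) - mu)^2 * px)
    vals["glcm_energy"] <- sum(P^2)
    vals["glcm_contrast"] <- sum((I - J)^2 * P)
    if (var_m > 1e-12) {
      vals["glcm_correlation"] <- (sum(I * J * P) - mu^2) / var_m
    } else {
      vals["glcm_correlation"] <- 0
      flags["glcm_correlation"] <- TRUE
    }
    vals["glcm_homogeneity"] <- sum(P / (1 + abs(I - J)))
    vals["glcm_variance"] <- sum((I - mu)^2 * P)
    vals["glcm_sum_average"] <- sum((I + J) * P)
    pos <- P > 0
    vals["glcm_entropy"] <- -sum(P[pos] * log2(P[pos]))
    vals["glcm_dissimilarity"] <- sum(abs(I - J) * P)
  }

  ## ---- GLRLM ----
  R <- m$glrlm
  Nr <- sum(R)
  Np <- m$n_voxels
  if (Nr > 0) {
    i <- row(R)
    j <- col(R)
    lv <- seq_len(nrow(R))
    rl <- seq_len(ncol(R))
    vals["glrlm_sre"] <- sum(R / j^2) / Nr
    vals["glrlm_lre"] <- sum(R * j^2) / Nr
    vals["glrlm_gln"] <- sum(rowSums(R)^2) / Nr
    vals["glrlm_rln"] <- sum(colSums(R)^2) / Nr
    vals["glrlm_rp"] <- Nr / (13 * Np)
    vals["glrlm_lgre"] <- sum(R / i^2) / Nr
    vals["glrlm_hgre"] <- sum(R * i^2) / Nr
    vals["glrlm_srlge"] <- sum(R / (i^2 * j^2)) / Nr
    vals["glrlm_srhge"] <- sum(R * i^2 / j^2) / Nr
    vals["glrlm_lrlge"] <- sum(R * j^2 / i^2) / Nr
    vals["glrlm_lrhge"] <- sum(R * i^2 * j^2) / Nr
    pr <- R / Nr
    mu_i <- sum(i * pr)
    mu_j <- sum(j * pr)
    vals["glrlm_glv"] <- sum((i - mu_i)^2 * pr)
    vals["glrlm_rlv"] <- sum((j - mu_j)^2 * pr)
  } else {
    flags[startsWith(names(flags), "glrlm_")] <- TRUE
  }

  ## ---- GLSZM (zone analogues of the run features) ----
  Z <- m$glszm
  Nz <- sum(Z)
  if (Nz > 0) {
    i <- row(Z)
    j <- col(Z)
    vals["glszm_sze"] <- sum(Z / j^2) / Nz
    vals["glszm_lze"] <- sum(Z * j^2) / Nz
    vals["glszm_gln"] <- sum(rowSums(Z)^2) / Nz
    vals["glszm_zsn"] <- sum(colSums(Z)^2) / Nz
    vals["glszm_zp"] <- Nz / Np
    vals["glszm_lgze"] <- sum(Z / i^2) / Nz
    vals["glszm_hgze"] <- sum(Z * i^2) / Nz
    vals["glszm_szlge"] <- sum(Z / (i^2 * j^2)) / Nz
    vals["glszm_szhge"] <- sum(Z * i^2 / j^2) / Nz
    vals["glszm_lzlge"] <- sum(Z * j^2 / i^2) / Nz
    vals["glszm_lzhge"] <- sum(Z * i^2 * j^2) / Nz
    pz <- Z / Nz
    mu_i <- sum(i * pz)
    mu_j <- sum(j * pz)
    vals["glszm_glv"] <- sum((i - mu_i)^2 * pz)
    vals["glszm_zsv"] <- sum((j - mu_j)^2 * pz)
  } else {
    flags[startsWith(names(flags), "glszm_")] <- TRUE
  }

  ## ---- NGTDM (Amadasun-Kline) ----
  g <- m$ngtdm
  n_tot <- sum(g$n)
  eps <- .ngtdm_eps
  if (n_tot > 0) {
    pres <- g$p > 0
    lv <- g$level[pres]
    p <- g$p[pres]
    s <- g$s[pres]
    Ngp <- sum(pres)
    vals["ngtdm_coarseness"] <- 1 / (eps + sum(p * s))
    if (Ngp > 1) {
      dif2 <- outer(lv, lv, function(a, b) (a - b)^2)
      vals["ngtdm_contrast"] <-
        sum(outer(p, p) * dif2) / (Ngp * (Ngp - 1)) * sum(s) / n_tot
      denom <- sum(abs(outer(lv * p, lv * p, `-`)))
      vals["ngtdm_busyness"] <- sum(p * s) / (eps + denom)
      ps <- p * s
      vals["ngtdm_complexity"] <-
        sum(abs(outer(lv, lv, `-`)) * outer(ps, ps, `+`) /
              (n_tot * outer(p, p, `+`)))
      vals["ngtdm_strength"] <-
        sum(outer(p, p, `+`) * dif2) / (eps + sum(s))
    } else {
      flags[c("ngtdm_contrast", "ngtdm_busyness")] <- TRUE
      vals["ngtdm_coarseness"] <- 1 / (eps + sum(p * s))
      vals["ngtdm_complexity"] <- 0
      vals["ngtdm_strength"] <- 0
    }
  } else {
    vals["ngtdm_coarseness"] <- 1 / eps
    flags[startsWith(names(flags), "ngtdm_")] <- TRUE
  }

  if (m$texture_degenerate) flags[] <- TRUE
  list(values = vals, flags = flags)
}

#' Extract the full 57-feature vector for one region of one modality volume
#'
#' Quantizes the region, builds the texture-count structures and concatenates
#' intensity and texture features in catalogue order.
#'
#' @inheritParams quantize_region
#' @param modality modality name recorded in the result.
#' @param min_voxels regions smaller than this have every feature flagged so
#'   downstream assembly can impute them from training medians (default 10).
#' @return Object of class `region_feature_vector` with `values` (57 named
#'   scalars), `flags`, `region_id`, `modality`, `n_voxels`.
#' @export
extract_region_features <- function(volume, label_map, region_id, modality,
                                    n_levels = 32, min_voxels = 10) {
  q <- quantize_region(volume, label_map, region_id, n_levels)
  m <- build_matrices(q)
  fi <- intensity_features(q)
  ft <- texture_features(m)
  values <- c(fi$values, ft$values)
  flags <- c(fi$flags, ft$flags)
  if (q$n_voxels < min_voxels) flags[] <- TRUE
  stopifnot(length(values) == 57L, all(is.finite(values)))
  structure(list(values = values, flags = flags, region_id = region_id,
                 modality = modality, n_voxels = q$n_voxels),
            class = "region_feature_vector")
}
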