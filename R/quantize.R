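#' Quantize a region's intensities to discrete gray levels
#'
#' Equal-width binning of in-region voxel intensities between the region
#' minimum and maximum into `n_levels` levels `1..n_levels`. Values exactly
#' at the maximum fall in the top level. A constant region maps entirely to
#' level 1 and is flagged degenerate. The quantized map is returned over the
#' region's bounding box with 0 marking out-of-region voxels, which is the
#' layout the texture-matrix counters expect.
#'
#' @param volume 3-D numeric array.
#' @param label_map 3-D integer array of the same shape; 0 = background.
#' @param region_id label to extract.
#' @param n_levels number of gray levels (>= 2); default 32.
#' @return An object of class `quantized_region` with fields `voxel_values`,
#'   `quantized_map` (bounding-box array, 0 outside the region), `n_levels`,
#'   `bin_edges`, `region_id`, `n_voxels` and `degenerate`.
#' @export
quantize_region <- function(volume, label_map, region_id, n_levels = 32) {
  if (!identical(dim(volume), dim(label_map))) {
    stop("volume and label_map must share one shape")
  }
  if (n_levels < 2) stop("n_levels must be >= 2")
  in_region <- label_map == region_id
  idx <- which(in_region)
  if (length(idx) == 0L) {
    stop(sprintf("region %s is empty", as.character(region_id)))
  }
  vals <- as.numeric(volume[idx])
  if (any(!is.finite(vals))) {
    stop(sprintf("region %s contains non-finite intensities",
                 as.character(region_id)))
  }
  lo <- min(vals)
  hi <- max(vals)
  degenerate <- hi <= lo
  if (degenerate) {
    lev <- rep.int(1L, length(vals))
    edges <- c(lo, lo + 1)  # placeholder single bin
    n_eff <- 1L
  } else {
    edges <- seq(lo, hi, length.out = n_levels + 1)
    lev <- pmin(findInterval(vals, edges, rightmost.closed = TRUE),
                n_levels)
    n_eff <- n_levels
  }
  # crop to the bounding box of the region
  coords <- arrayInd(idx, dim(volume))
  rng <- apply(coords, 2, range)
  box_dim <- rng[2, ] - rng[1, ] + 1L
  qmap <- array(0L, dim = box_dim)
  qmap[cbind(coords[, 1] - rng[1, 1] + 1L,
             coords[, 2] - rng[1, 2] + 1L,
             coords[, 3] - rng[1, 3] + 1L)] <- as.integer(lev)
  structure(list(voxel_values = vals, quantized_map = qmap,
                 n_levels = as.integer(n_levels), bin_edges = edges,
                 region_id = region_id, n_voxels = length(vals),
                 degenerate = degenerate),
            class = "quantized_region")
}

#' Build the four texture-count structures for a quantized region
#'
#' Counts are 3-D and respect the region mask throughout: out-of-region
#' voxels never contribute to pairs, runs, zones or neighborhoods.
#'
#' * GLCM: symmetric co-occurrence counts at the 13 unique distance-1
#'   offsets, summed over offsets (each unordered pair enters both orders).
#' * GLRLM: maximal same-level runs along the same 13 directions, summed.
#' * GLSZM: 26-connected constant-level zones, indexed level x zone size.
#' * NGTDM: per level, the count `n_i` of voxels having at least one
#'   in-region 26-neighbor, the probability `p_i = n_i / sum(n)`, and the
#'   summed absolute difference `s_i` between the voxel level and the mean
#'   level of its in-region neighbors.
#'
#' @param q a [quantize_region()] result.
#' @return An object of class `texture_matrices` with raw counts (`glcm`,
#'   `glrlm`, `glszm`, `ngtdm`), the normalized GLCM (`glcm_norm`), and the
#'   flag `texture_degenerate` for single-voxel regions.
#' @export
build_matrices <- function(q) {
  stopifnot(inherits(q, "quantized_region"))
  counts <- texture_counts_cpp(q$quantized_map, q$n_levels)
  glcm <- counts$glcm
  tot <- sum(glcm)
  glcm_norm <- if (tot > 0) glcm / tot else glcm
  ngtdm_n <- counts$ngtdm_n
  n_tot <- sum(ngtdm_n)
  ngtdm <- data.frame(level = seq_len(q$n_levels),
                      n = ngtdm_n,
                      p = if (n_tot > 0) ngtdm_n / n_tot else ngtdm_n,
                      s = counts$ngtdm_s)
  structure(list(glcm = glcm, glcm_norm = glcm_norm,
                 glrlm = counts$glrlm, glszm = counts$glszm,
                 ngtdm = ngtdm, n_levels = q$n_levels,
                 n_voxels = q$n_voxels,
                 texture_degenerate = q$n_voxels < 2L || tot == 0),
            class = "texture_matrices")
}
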