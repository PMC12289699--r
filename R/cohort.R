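#' Group-level effect settings for the synthetic cohort generator
#'
#' Describes how diagnostic groups differ in the phantom cohort. Each group
#' gets an additive intensity offset (`mean_shift`, arbitrary units), a
#' spatial correlation scale for its noise texture (`smoothness`, voxels;
#' the standard deviation of the Gaussian smoothing kernel applied to white
#' noise), and a voxel noise standard deviation (`noise_sd`, after
#' smoothing the field is rescaled to this marginal SD). Modalities differ by
#' a multiplicative `modality_gain`.
#'
#' The defaults encode a three-group design (HC, MCI, AD) in which group
#' means are separated by 1 and 2 noise standard deviations and the noise
#' correlation length grows by a factor of 1.5 from controls to the most
#' affected group, so both intensity and texture features carry signal.
#'
#' @param mean_shift named numeric, additive offset per group.
#' @param smoothness named numeric, Gaussian smoothing sigma (voxels) per
#'   group; 0 gives uncorrelated noise.
#' @param noise_sd named numeric, marginal noise SD per group; must be > 0.
#' @param modality_gain named numeric, multiplicative factor per modality.
#' @return An object of class `group_effect`.
#' @export
#' @examples
#' group_effect(mean_shift = c(HC = 0, MCI = 1, AD = 2))
group_effect <- function(mean_shift = c(HC = 0, MCI = 1, AD = 2),
                         smoothness = c(HC = 1, MCI = 1.25, AD = 1.5),
                         noise_sd = c(HC = 1, MCI = 1, AD = 1),
                         modality_gain = c(T1 = 1, T2 = 0.9, FLAIR = 1.1)) {
  stopifnot(is.numeric(mean_shift), is.numeric(smoothness),
            is.numeric(noise_sd), is.numeric(modality_gain))
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0 for every group")
  if (any(smoothness < 0)) stop("smoothness must be >= 0")
  structure(list(mean_shift = mean_shift, smoothness = smoothness,
                 noise_sd = noise_sd, modality_gain = modality_gain),
            class = "group_effect")
}

# look up a per-group (or per-modality) parameter that may be scalar or named
effect_param <- function(v, key, what) {
  if (length(v) == 1L && is.null(names(v))) return(unname(v))
  if (!key %in% names(v)) {
    stop(sprintf("no %s entry for '%s'", what, key))
  }
  unname(v[[key]])
}

#' Specification of a synthetic multimodal cohort
#'
#' Bundles everything needed to regenerate a phantom cohort: grid geometry,
#' parcellation size, group design, modality list, effect settings and the
#' master seed. Per-subject seeds are derived as `seed + subject index`, so
#' the whole cohort is reproducible from this object alone.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param group_labels ordered, distinct group labels.
#' @param grid_shape integer vector of 3 voxel dimensions.
#' @param voxel_size_mm isotropic voxel spacing, recorded as metadata.
#' @param n_regions number of parcels in the synthetic parcellation (>= 1).
#' @param modalities ordered modality names.
#' @param effect a [group_effect()] object.
#' @param seed master seed (integer).
#' @param baseline constant foreground intensity before group/modality
#'   effects are applied.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = 3, grid_shape = c(24, 24, 12),
#'                     n_regions = 4, seed = 1)
cohort_spec <- function(n_per_group = 30,
                        group_labels = c("HC", "MCI", "AD"),
                        grid_shape = c(64, 64, 32),
                        voxel_size_mm = 1,
                        n_regions = 26,
                        modalities = c("T1", "T2", "FLAIR"),
                        effect = group_effect(),
                        seed = 20240101,
                        baseline = 100) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (anyDuplicated(group_labels)) stop("group labels must be distinct")
  if (length(grid_shape) != 3 || any(grid_shape < 2)) {
    stop("grid_shape must be three dimensions, each >= 2")
  }
  if (!inherits(effect, "group_effect")) stop("effect must be a group_effect")
  grid_shape <- as.integer(grid_shape)
  # quick feasibility check: the ellipsoidal foreground occupies about
  # pi/6 * 0.9^3 of the grid; every region must be able to receive 50 voxels
  approx_fg <- prod(grid_shape) * pi / 6 * 0.9^3
  if (approx_fg / n_regions < 50) {
    stop(sprintf(
      "grid %s too small: region %d cannot receive 50 voxels (~%.0f available per region)",
      paste(grid_shape, collapse = "x"), n_regions, approx_fg / n_regions))
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 group_labels = group_labels,
                 grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm,
                 n_regions = as.integer(n_regions),
                 modalities = modalities,
                 effect = effect,
                 seed = as.integer(seed),
                 baseline = baseline),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec\n")
  cat(sprintf("  groups    : %s (n = %d each)\n",
              paste(x$group_labels, collapse = ", "), x$n_per_group))
  cat(sprintf("  grid      : %s voxels (%g mm)\n",
              paste(x$grid_shape, collapse = " x "), x$voxel_size_mm))
  cat(sprintf("  regions   : %d\n", x$n_regions))
  cat(sprintf("  modalities: %s\n", paste(x$modalities, collapse = ", ")))
  cat(sprintf("  seed      : %d\n", x$seed))
  invisible(x)
}

#' Generate the shared synthetic parcellation
#'
#' Builds a 3-D integer label map on the grid of a [cohort_spec()]: an ellipsoidal
#' foreground (semi-axes 45% of each grid dimension) partitioned into
#' `n_regions` contiguous parcels by nearest-seed (Voronoi) assignment from
#' seed points drawn inside the foreground. Background voxels are 0; labels
#' are exactly `1..n_regions`. Seed layouts leaving any parcel under 50
#' voxels are redrawn (deterministically); if no layout works the offending
#' region is reported.
#'
#' @param spec a [cohort_spec()].
#' @return 3-D integer array of labels.
#' @export
generate_label_map <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  dims <- spec$grid_shape
  ctr <- (dims + 1) / 2
  semi <- 0.45 * dims
  ax <- ((seq_len(dims[1]) - ctr[1]) / semi[1])^2
  ay <- ((seq_len(dims[2]) - ctr[2]) / semi[2])^2
  az <- ((seq_len(dims[3]) - ctr[3]) / semi[3])^2
  fg <- outer(outer(ax, ay, `+`), az, `+`) <= 1
  fg_idx <- which(fg)
  n_fg <- length(fg_idx)
  if (n_fg < 50 * spec$n_regions) {
    stop(sprintf(
      "grid too small: region %d cannot receive 50 voxels (foreground has %d voxels for %d regions)",
      spec$n_regions, n_fg, spec$n_regions))
  }
  coords <- arrayInd(fg_idx, dims)
  lab <- with_seed(spec$seed, {
    res <- NULL
    for (attempt in seq_len(25L)) {
      seeds <- coords[sample.int(n_fg, spec$n_regions), , drop = FALSE]
      best_d <- rep(Inf, n_fg)
      assign_lab <- integer(n_fg)
      for (r in seq_len(spec$n_regions)) {
        d <- (coords[, 1] - seeds[r, 1])^2 + (coords[, 2] - seeds[r, 2])^2 +
          (coords[, 3] - seeds[r, 3])^2
        upd <- d < best_d
        best_d[upd] <- d[upd]
        assign_lab[upd] <- r
      }
      sizes <- tabulate(assign_lab, nbins = spec$n_regions)
      if (all(sizes >= 50L)) {
        res <- assign_lab
        break
      }
    }
    if (is.null(res)) {
      stop(sprintf(
        "grid too small: region %d cannot receive 50 voxels under any seed layout tried",
        which.min(sizes)))
    }
    res
  })
  out <- array(0L, dim = dims)
  out[fg_idx] <- lab
  out
}

# separable 3-D Gaussian smoothing; kernel truncated at 3 sigma and
# row-renormalized at the boundaries so constant fields are preserved
smooth_gaussian3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  dims <- dim(vol)
  kern_mat <- function(n) {
    half <- max(1L, ceiling(3 * sigma))
    i <- seq_len(n)
    K <- outer(i, i, function(a, b) {
      d <- abs(a - b)
      ifelse(d <= half, exp(-d^2 / (2 * sigma^2)), 0)
    })
    K / rowSums(K)
  }
  # contract along each dimension in turn
  m <- matrix(vol, dims[1], dims[2] * dims[3])
  vol <- array(kern_mat(dims[1]) %*% m, dims)
  v2 <- aperm(vol, c(2, 1, 3))
  m <- matrix(v2, dims[2], dims[1] * dims[3])
  v2 <- array(kern_mat(dims[2]) %*% m, dim(v2))
  vol <- aperm(v2, c(2, 1, 3))
  v3 <- aperm(vol, c(3, 1, 2))
  m <- matrix(v3, dims[3], dims[1] * dims[2])
  v3 <- array(kern_mat(dims[3]) %*% m, dim(v3))
  aperm(v3, c(2, 3, 1))
}

#' Generate one synthetic subject
#'
#' Each modality volume is `gain * (baseline + mean_shift + noise)` where the
#' noise field is white Gaussian noise smoothed with the group's `smoothness`
#' sigma and rescaled to the group's `noise_sd`. Modalities receive
#' independent noise draws. The result is reproducible from
#' `(spec$seed, subject_seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param group group label, one of `spec$group_labels`.
#' @param subject_seed integer seed offset for this subject.
#' @param label_map shared parcellation from [generate_label_map()]; computed
#'   on the fly if omitted (wasteful inside a cohort loop).
#' @param subject_id subject identifier string.
#' @return A `subject_image_set`: named modality volumes plus the label map.
#' @export
generate_subject <- function(spec, group, subject_seed,
                             label_map = NULL,
                             subject_id = sprintf("S%04d", subject_seed)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% spec$group_labels) {
    stop(sprintf("unknown group label '%s' (expected one of %s)", group,
                 paste(spec$group_labels, collapse = ", ")))
  }
  if (is.null(label_map)) label_map <- generate_label_map(spec)
  eff <- spec$effect
  shift <- effect_param(eff$mean_shift, group, "mean_shift")
  sig <- effect_param(eff$smoothness, group, "smoothness")
  nsd <- effect_param(eff$noise_sd, group, "noise_sd")
  dims <- spec$grid_shape
  volumes <- with_seed(spec$seed + subject_seed, {
    lapply(setNames(spec$modalities, spec$modalities), function(mod) {
      gain <- effect_param(eff$modality_gain, mod, "modality_gain")
      field <- smooth_gaussian3d(array(rnorm(prod(dims)), dims), sig)
      field <- field / sd(field) * nsd
      gain * (spec$baseline + shift + field)
    })
  })
  structure(list(subject_id = subject_id, group = group,
                 volumes = volumes, label_map = label_map,
                 seed = spec$seed + subject_seed),
            class = "subject_image_set")
}

#' @export
print.subject_image_set <- function(x, ...) {
  cat(sprintf("Subject %s (group %s): %d modalities, grid %s, %d regions\n",
              x$subject_id, x$group, length(x$volumes),
              paste(dim(x$label_map), collapse = "x"),
              length(setdiff(unique(as.vector(x$label_map)), 0L))))
  invisible(x)
}

#' Simulate a full cohort in memory
#'
#' Generates the shared label map and all subjects (groups in the order of
#' `spec$group_labels`, `spec$n_per_group` subjects each, subject seeds
#' `1..N` in manifest order).
#'
#' @param spec a [cohort_spec()].
#' @return List with `subjects` (list of `subject_image_set`), `label_map`,
#'   and a `manifest` data frame (subject_id, group, seed).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  label_map <- generate_label_map(spec)
  groups <- rep(spec$group_labels, each = spec$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(spec, groups[i], subject_seed = i,
                                      label_map = label_map,
                                      subject_id = ids[i])
  }
  manifest <- data.frame(subject_id = ids, group = groups,
                         seed = spec$seed + seq_len(n),
                         stringsAsFactors = FALSE)
  list(subjects = subjects, label_map = label_map, manifest = manifest)
}

#' Generate a cohort and write it to disk as NIfTI + manifest CSV
#'
#' Writes one `.nii.gz` per subject and modality, the shared label map, and
#' `manifest.csv` with columns `subject_id, group, <one path column per
#' modality>, label_map, seed`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return The manifest data frame, invisibly; also written as CSV.
#' @export
generate_cohort <- function(spec, out_dir) {
  cohort <- simulate_cohort(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  pd <- rep(spec$voxel_size_mm, 3)
  lm_path <- file.path(out_dir, "label_map.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(cohort$label_map, pixdim = pd), lm_path)
  man <- cohort$manifest
  for (mod in spec$modalities) man[[paste0("path_", mod)]] <- NA_character_
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    for (mod in spec$modalities) {
      p <- file.path(out_dir, sprintf("%s_%s.nii.gz", s$subject_id, mod))
      RNifti::writeNifti(RNifti::asNifti(s$volumes[[mod]], pixdim = pd), p)
      man[[paste0("path_", mod)]][i] <- p
    }
  }
  man$label_map <- lm_path
  man <- man[, c("subject_id", "group", paste0("path_", spec$modalities),
                 "label_map", "seed")]
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort written by [generate_cohort()] back into memory
#'
#' @param manifest manifest data frame or path to `manifest.csv`.
#' @param modalities modalities to load; default all `path_*` columns.
#' @return List with `subjects`, `label_map` and `manifest`, as
#'   [simulate_cohort()].
#' @export
read_cohort <- function(manifest, modalities = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  path_cols <- grep("^path_", names(manifest), value = TRUE)
  mods <- sub("^path_", "", path_cols)
  if (!is.null(modalities)) {
    missing <- setdiff(modalities, mods)
    if (length(missing)) {
      stop("manifest has no path column for modality: ",
           paste(missing, collapse = ", "))
    }
    mods <- modalities
  }
  lm_path <- unique(manifest$label_map)
  if (length(lm_path) != 1) stop("manifest must share one label map")
  if (!file.exists(lm_path)) stop("label map file not found: ", lm_path)
  label_map <- array(as.integer(round(RNifti::readNifti(lm_path))),
                     dim = dim(RNifti::readNifti(lm_path)))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    vols <- lapply(setNames(mods, mods), function(mod) {
      p <- manifest[[paste0("path_", mod)]][i]
      if (!file.exists(p)) {
        stop(sprintf("subject %s: missing file for modality %s: %s",
                     manifest$subject_id[i], mod, p))
      }
      v <- RNifti::readNifti(p)
      array(as.numeric(v), dim = dim(v))
    })
    structure(list(subject_id = manifest$subject_id[i],
                   group = manifest$group[i], volumes = vols,
                   label_map = label_map,
                   seed = manifest$seed[i] %||% NA_integer_),
              class = "subject_image_set")
  })
  list(subjects = subjects, label_map = label_map, manifest = manifest)
}
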