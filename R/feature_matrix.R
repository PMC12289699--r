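#' Assemble the feature row for one subject
#'
#' Concatenates 57-feature blocks over modalities (outer loop) and regions
#' (inner loop) in a fixed order, so a single-modality, 26-region row has
#' length 26 x 57 = 1482 and the three-modality row 4446.
#'
#' @param subject a `subject_image_set`.
#' @param modalities modalities to use; default all present.
#' @param n_levels gray levels for quantization.
#' @param min_voxels minimum region size before wholesale flagging.
#' @param regions region ids; default all positive labels in the label map.
#' @return List with `values`, `flags` and the column metadata data frame
#'   `columns` (modality, region, feature).
#' @export
assemble_subject <- function(subject, modalities = NULL, n_levels = 32,
                             min_voxels = 10, regions = NULL) {
  stopifnot(inherits(subject, "subject_image_set"))
  if (is.null(modalities)) modalities <- names(subject$volumes)
  missing <- setdiff(modalities, names(subject$volumes))
  if (length(missing)) {
    stop(sprintf("subject %s: missing modality %s", subject$subject_id,
                 paste(missing, collapse = ", ")))
  }
  if (is.null(regions)) {
    regions <- sort(setdiff(unique(as.vector(subject$label_map)), 0L))
  }
  feat <- feature_catalogue()$name
  blocks <- lapply(modalities, function(mod) {
    vol <- subject$volumes[[mod]]
    lapply(regions, function(r) {
      extract_region_features(vol, subject$label_map, r, mod,
                              n_levels = n_levels, min_voxels = min_voxels)
    })
  })
  values <- unlist(lapply(blocks, function(b) {
    unlist(lapply(b, `[[`, "values"), use.names = FALSE)
  }), use.names = FALSE)
  flags <- unlist(lapply(blocks, function(b) {
    unlist(lapply(b, `[[`, "flags"), use.names = FALSE)
  }), use.names = FALSE)
  columns <- data.frame(
    modality = rep(modalities, each = length(regions) * length(feat)),
    region = rep(rep(regions, each = length(feat)), times = length(modalities)),
    feature = rep(feat, times = length(regions) * length(modalities)),
    stringsAsFactors = FALSE)
  columns$name <- feature_column_name(columns$modality, columns$region,
                                      columns$feature)
  names(values) <- columns$name
  names(flags) <- columns$name
  list(values = values, flags = flags, columns = columns)
}

#' Encode/decode feature-matrix column names
#'
#' Column names are `"<modality>|r<region>|<feature>"`; the mapping between a
#' name and its (modality, region, feature) triple is a bijection.
#'
#' @param modality,region,feature vectors of equal length.
#' @return Character vector of column names.
#' @export
feature_column_name <- function(modality, region, feature) {
  sprintf("%s|r%02d|%s", modality, as.integer(region), feature)
}

#' @rdname feature_column_name
#' @param name column names to decode.
#' @export
parse_column_name <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed column name: ", name[bad][1])
  data.frame(modality = vapply(parts, `[[`, "", 1L),
             region = as.integer(sub("^r", "", vapply(parts, `[[`, "", 2L))),
             feature = vapply(parts, `[[`, "", 3L),
             name = name, stringsAsFactors = FALSE)
}

#' Build the cohort feature matrix
#'
#' Extracts every subject's feature row (manifest order) into a
#' subjects x features matrix with group labels, per-cell degeneracy flags
#' and column metadata. No imputation happens here: flagged cells keep their
#' substituted values and are re-imputed from training medians inside each
#' training partition (see [fit_imputer()]), which keeps evaluation free of
#' train/test leakage.
#'
#' @param cohort a cohort list from [simulate_cohort()] / [read_cohort()], or
#'   a path to a `manifest.csv` written by [generate_cohort()].
#' @param modalities modalities to extract; default all.
#' @param n_levels,min_voxels extraction settings (see
#'   [extract_region_features()]).
#' @return Object of class `feature_matrix` with fields `x`, `flags`,
#'   `subject_id`, `group`, `columns`, `settings`.
#' @export
build_feature_matrix <- function(cohort, modalities = NULL, n_levels = 32,
                                 min_voxels = 10) {
  if (is.character(cohort)) cohort <- read_cohort(cohort, modalities)
  subjects <- cohort$subjects
  stopifnot(length(subjects) >= 1)
  first <- assemble_subject(subjects[[1]], modalities, n_levels, min_voxels)
  x <- matrix(NA_real_, nrow = length(subjects), ncol = length(first$values),
              dimnames = list(vapply(subjects, `[[`, "", "subject_id"),
                              first$columns$name))
  fl <- matrix(NA, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
  x[1, ] <- first$values
  fl[1, ] <- first$flags
  if (length(subjects) > 1) {
    for (i in 2:length(subjects)) {
      row <- assemble_subject(subjects[[i]], modalities, n_levels, min_voxels)
      stopifnot(identical(row$columns$name, first$columns$name))
      x[i, ] <- row$values
      fl[i, ] <- row$flags
    }
  }
  structure(list(x = x, flags = fl,
                 subject_id = rownames(x),
                 group = vapply(subjects, `[[`, "", "group"),
                 columns = first$columns,
                 settings = list(n_levels = n_levels,
                                 min_voxels = min_voxels,
                                 modalities = unique(first$columns$modality))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d subjects x %d features (%s; %d regions x 57)\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$columns$modality), collapse = ", "),
              length(unique(x$columns$region))))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Restrict a feature matrix to a subset of modalities
#'
#' @param fm a `feature_matrix`.
#' @param modalities modalities to keep.
#' @return A `feature_matrix` with only the requested modality columns.
#' @export
subset_modalities <- function(fm, modalities) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing <- setdiff(modalities, unique(fm$columns$modality))
  if (length(missing)) {
    stop("feature matrix has no modality: ", paste(missing, collapse = ", "))
  }
  keep <- fm$columns$modality %in% modalities
  fm$x <- fm$x[, keep, drop = FALSE]
  fm$flags <- fm$flags[, keep, drop = FALSE]
  fm$columns <- fm$columns[keep, , drop = FALSE]
  fm$settings$modalities <- modalities
  fm
}

#' Training-median imputer for flagged cells
#'
#' Learns, per column, the median of the non-flagged training cells; applying
#' the imputer replaces flagged cells by that median. Columns whose training
#' cells are all flagged keep their substituted values (the degeneracy
#' policy already guarantees finiteness).
#'
#' @param fm a `feature_matrix`.
#' @param rows training row indices; default all rows.
#' @return An `imputer` (named median vector + column names).
#' @export
fit_imputer <- function(fm, rows = seq_len(nrow(fm$x))) {
  x <- fm$x[rows, , drop = FALSE]
  fl <- fm$flags[rows, , drop = FALSE]
  med <- vapply(seq_len(ncol(x)), function(j) {
    ok <- !fl[, j]
    if (any(ok)) median(x[ok, j]) else NA_real_
  }, numeric(1))
  structure(list(medians = setNames(med, colnames(x))), class = "imputer")
}

#' @rdname fit_imputer
#' @param imp an `imputer`.
#' @param x value matrix to impute.
#' @param flags logical matrix marking cells to replace.
#' @export
apply_imputer <- function(imp, x, flags) {
  stopifnot(inherits(imp, "imputer"), identical(dim(x), dim(flags)))
  for (j in which(apply(flags, 2, any))) {
    m <- imp$medians[[j]]
    if (!is.na(m)) x[flags[, j], j] <- m
  }
  x
}

#' Write / read a feature matrix as wide CSV plus JSON sidecar
#'
#' The CSV holds `subject_id`, `group` and one column per feature; the
#' sidecar records column metadata, per-cell flags (as indices) and the
#' extraction settings.
#'
#' @param fm a `feature_matrix`.
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(subject_id = fm$subject_id, group = fm$group,
                   fm$x, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(columns = fm$columns, settings = fm$settings,
               flagged_cells = which(fm$flags, arr.ind = TRUE))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(prefix) {
  df <- read.csv(paste0(prefix, ".csv"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$subject_id
  fl <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  if (length(side$flagged_cells)) {
    fl[as.matrix(side$flagged_cells)] <- TRUE
  }
  structure(list(x = x, flags = fl, subject_id = df$subject_id,
                 group = df$group, columns = as.data.frame(side$columns),
                 settings = side$settings),
            class = "feature_matrix")
}

#' Long-format view of a feature matrix
#'
#' One row per (subject, modality, region, feature) with the value and its
#' degeneracy flag — the tidy export format for downstream tooling.
#'
#' @param fm a `feature_matrix`.
#' @return Data frame with columns subject_id, group, modality, region_id,
#'   feature_name, value, flag.
#' @export
as_tidy_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$x)
  p <- ncol(fm$x)
  data.frame(subject_id = rep(fm$subject_id, times = p),
             group = rep(fm$group, times = p),
             modality = rep(fm$columns$modality, each = n),
             region_id = rep(fm$columns$region, each = n),
             feature_name = rep(fm$columns$feature, each = n),
             value = as.vector(fm$x),
             flag = as.vector(fm$flags),
             stringsAsFactors = FALSE)
}
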