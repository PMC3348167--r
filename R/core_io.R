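#' Brain mask linking 3-D voxels to matrix columns
#'
#' A `brain_mask` fixes the correspondence between the voxels of a 3-D
#' gray-matter density grid and the columns of a subject-by-voxel matrix.
#' Flat voxel indices are 1-based and column-major over the grid (the native
#' R array order, as produced by [which()] on the mask array), so column `j`
#' of a cohort matrix always refers to the same 3-D location in every module.
#'
#' @param in_mask logical 3-D array; `TRUE` marks voxels inside the analysis
#'   mask.
#' @return An object of class `brain_mask` with fields `grid_shape`,
#'   `in_mask`, `vox_index` (array index of each mask voxel, ascending) and
#'   `n_voxels`.
#' @examples
#' m <- brain_mask(array(TRUE, c(4, 4, 4)))
#' m$n_voxels
#' @export
brain_mask <- function(in_mask) {
  if (!is.logical(in_mask) || length(dim(in_mask)) != 3L) {
    stop("'in_mask' must be a logical 3-D array")
  }
  vox_index <- which(in_mask)
  if (length(vox_index) == 0L) {
    stop("empty mask: no voxels survive")
  }
  lut <- integer(length(in_mask))
  lut[vox_index] <- seq_along(vox_index)
  structure(
    list(grid_shape = dim(in_mask), in_mask = in_mask,
         vox_index = vox_index, n_voxels = length(vox_index),
         .lut = lut),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: grid %s, %d voxels in mask\n",
              paste(x$grid_shape, collapse = "x"), x$n_voxels))
  invisible(x)
}

#' Map mask columns to 3-D voxel coordinates and back
#'
#' @param mask a [brain_mask()].
#' @param cols integer vector of column indices (1..V).
#' @return `mask_coords()`: an integer matrix with columns `x`, `y`, `z`
#'   (1-based grid coordinates). `coords_to_cols()`: the column indices, with
#'   `NA` for coordinates outside the mask.
#' @export
mask_coords <- function(mask, cols) {
  stopifnot(inherits(mask, "brain_mask"))
  if (any(cols < 1L | cols > mask$n_voxels)) {
    stop("column index outside 1..V")
  }
  co <- arrayInd(mask$vox_index[cols], mask$grid_shape)
  colnames(co) <- c("x", "y", "z")
  co
}

#' @param coords integer matrix with one row per voxel and columns x, y, z.
#' @rdname mask_coords
#' @export
coords_to_cols <- function(mask, coords) {
  stopifnot(inherits(mask, "brain_mask"))
  coords <- matrix(as.integer(coords), ncol = 3L)
  flat <- coords[, 1L] +
    (coords[, 2L] - 1L) * mask$grid_shape[1L] +
    (coords[, 3L] - 1L) * prod(mask$grid_shape[1:2])
  out <- mask$.lut[flat]
  out[out == 0L] <- NA_integer_
  out
}

#' Build an analysis mask from mean gray-matter density
#'
#' A voxel enters the mask when its mean density across subjects exceeds
#' `threshold`, a stand-in for the implicit masking that segmentation
#' pipelines apply before voxel-based morphometry.
#'
#' @param volumes a list of 3-D arrays, or a 4-D array whose last dimension
#'   indexes subjects.
#' @param threshold mean-density cutoff (default 0.1).
#' @return A [brain_mask()].
#' @export
make_mask <- function(volumes, threshold = 0.1) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    volumes <- lapply(seq_len(dim(volumes)[4L]), function(i) volumes[, , , i])
  }
  if (!is.list(volumes) || length(volumes) == 0L) {
    stop("'volumes' must be a non-empty list of 3-D arrays or a 4-D array")
  }
  d <- dim(volumes[[1L]])
  mean_vol <- Reduce(`+`, volumes) / length(volumes)
  brain_mask(array(mean_vol > threshold, d))
}

#' Cohort of gray-matter density maps
#'
#' Bundles the subject-by-voxel density matrix `X` with per-subject ages,
#' binary cohort labels (+1 young, -1 old) and the [brain_mask()] that links
#' columns to 3-D voxels. This is the container every downstream step
#' operates on; the label vector plays the role of the target the sparse
#' representation reconstructs.
#'
#' @param X numeric matrix, subjects in rows, mask voxels in columns.
#' @param ages numeric vector of ages in years.
#' @param labels integer vector of +1 (young) / -1 (old).
#' @param mask a [brain_mask()] with `n_voxels == ncol(X)`.
#' @param subject_ids optional character vector of subject identifiers.
#' @return An object of class `vbm_cohort`.
#' @export
vbm_cohort <- function(X, ages, labels, mask, subject_ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(ages) || nrow(X) != length(labels)) {
    stop("rows of X must match length of 'ages' and 'labels'")
  }
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1")
  stopifnot(inherits(mask, "brain_mask"))
  if (ncol(X) != mask$n_voxels) {
    stop("columns of X must match the number of mask voxels")
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(X)))
  structure(
    list(X = X, ages = as.numeric(ages), labels = as.integer(labels),
         mask = mask, subject_ids = as.character(subject_ids)),
    class = "vbm_cohort"
  )
}

#' @export
print.vbm_cohort <- function(x, ...) {
  cat(sprintf("vbm_cohort: %d subjects (%d young, %d old), %d voxels, ages %.0f-%.0f\n",
              nrow(x$X), sum(x$labels == 1L), sum(x$labels == -1L),
              ncol(x$X), min(x$ages), max(x$ages)))
  invisible(x)
}

#' Load gray-matter density volumes into a cohort
#'
#' Reads one NIfTI volume per subject, checks that all volumes share the same
#' grid, and flattens the in-mask voxels into a subject-by-voxel matrix.
#' When no mask is supplied one is built from the mean density via
#' [make_mask()].
#'
#' @param volume_paths character vector of NIfTI file paths, one per subject.
#' @param subject_table data frame with columns `subject_id`, `age` and
#'   `group` (`"young"` or `"old"`), rows aligned with `volume_paths`.
#' @param mask optional [brain_mask()]; built from the data when absent.
#' @param mask_threshold mean-density cutoff passed to [make_mask()].
#' @return A [vbm_cohort()].
#' @export
load_gm_maps <- function(volume_paths, subject_table, mask = NULL,
                         mask_threshold = 0.1) {
  if (length(volume_paths) != nrow(subject_table)) {
    stop("'subject_table' rows must match 'volume_paths'")
  }
  req <- c("subject_id", "age", "group")
  if (!all(req %in% names(subject_table))) {
    stop("subject table needs columns: ", paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(subject_table$group), c("young", "old"))
  if (length(bad) > 0L) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'young' or 'old')")
  }
  vols <- vector("list", length(volume_paths))
  d0 <- NULL
  for (i in seq_along(volume_paths)) {
    v <- RNifti::readNifti(volume_paths[i])
    v <- array(as.numeric(v), dim(v))
    if (length(dim(v)) != 3L) {
      stop("volume is not 3-D: ", volume_paths[i])
    }
    if (is.null(d0)) d0 <- dim(v)
    if (!identical(dim(v), d0)) {
      stop(sprintf("grid shape mismatch in '%s': %s, expected %s",
                   volume_paths[i], paste(dim(v), collapse = "x"),
                   paste(d0, collapse = "x")))
    }
    vols[[i]] <- v
  }
  if (is.null(mask)) mask <- make_mask(vols, mask_threshold)
  if (!identical(dim(mask$in_mask), d0)) {
    stop("mask grid does not match the volumes")
  }
  X <- do.call(rbind, lapply(vols, function(v) as.numeric(v)[mask$vox_index]))
  labels <- ifelse(subject_table$group == "young", 1L, -1L)
  vbm_cohort(X, subject_table$age, labels, mask, subject_table$subject_id)
}

#' Write per-voxel scores back into image space
#'
#' Produces a NIfTI volume in which in-mask scored voxels carry their value
#' and every other voxel is 0 — the form used for weight maps and cluster
#' label maps.
#'
#' @param scores either a numeric vector of length V (one value per mask
#'   column) or a shorter numeric vector whose names are mask column indices.
#' @param mask a [brain_mask()].
#' @param out_path output NIfTI path (`.nii` or `.nii.gz`).
#' @return `out_path`, invisibly.
#' @export
save_score_map <- function(scores, mask, out_path) {
  stopifnot(inherits(mask, "brain_mask"))
  vol <- array(0, mask$grid_shape)
  if (is.null(names(scores))) {
    if (length(scores) != mask$n_voxels) {
      stop("unnamed 'scores' must have one value per mask voxel")
    }
    vol[mask$vox_index] <- as.numeric(scores)
  } else if (length(scores) > 0L) {
    cols <- as.integer(names(scores))
    if (anyNA(cols) || any(cols < 1L | cols > mask$n_voxels)) {
      stop("score names must be valid mask column indices (1..V)")
    }
    vol[mask$vox_index[cols]] <- as.numeric(scores)
  }
  RNifti::writeNifti(RNifti::asNifti(vol), out_path)
  invisible(out_path)
}

#' Read and write subject tables
#'
#' Tab-separated subject tables with columns `subject_id`, `age` and `group`
#' (`young`/`old`).
#'
#' @param path file path.
#' @return `read_subject_table()`: a data frame.
#' @export
read_subject_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "age", "group")
  if (!all(req %in% names(tab))) {
    stop("subject table needs columns: ", paste(req, collapse = ", "))
  }
  tab
}

#' @param table data frame with the three required columns.
#' @rdname read_subject_table
#' @export
write_subject_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
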