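#' Construct a voxel volume
#'
#' A `voxel_volume` is a rank-3 grid of 8-bit gray levels (0-255) together
#' with the physical voxel spacing in mm along each axis. Axis 1 is the
#' beam/depth direction (larger index = deeper beneath the transducer);
#' axes 2-3 are lateral. A C-view section is a constant-axis-1 slice, an
#' A-view plane contains axis 1.
#'
#' @param data rank-3 numeric/integer array with values in \[0, 255\].
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param clip if `TRUE`, values outside \[0, 255\] are clipped instead of
#'   raising an error.
#' @return object of class `voxel_volume` with elements `data` (integer
#'   array) and `spacing`.
#' @export
voxel_volume <- function(data, spacing = c(0.2, 0.2, 0.2), clip = FALSE) {
  stopifnot(length(dim(data)) == 3, all(dim(data) > 0))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0), all(is.finite(spacing)))
  data <- round(data)
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 255) {
    if (!clip) {
      stop("gray levels outside [0, 255]; pass clip = TRUE to clip", call. = FALSE)
    }
    data <- pmin(pmax(data, 0), 255)
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing, axes = "depth-first"),
            class = "voxel_volume")
}

#' Construct a lesion mask
#'
#' Binary segmentation co-registered with a [voxel_volume()]. The mask must
#' contain at least one foreground voxel; if it is fragmented into several
#' 26-connected components, only the largest is kept and a warning is issued.
#'
#' @param data rank-3 logical (or 0/1) array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return object of class `lesion_mask` with elements `data` (logical array)
#'   and `spacing`.
#' @export
lesion_mask <- function(data, spacing = c(0.2, 0.2, 0.2)) {
  stopifnot(length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  data <- data > 0
  if (!any(data)) stop("empty lesion mask", call. = FALSE)
  lab <- label_components(data, connectivity = 26)
  k <- max(lab)
  if (k > 1L) {
    warning(sprintf(
      "lesion mask has %d connected components; keeping the largest (%d of %d voxels)",
      k, sum(lab == 1L), sum(data)), call. = FALSE)
    data <- lab == 1L
  }
  structure(list(data = data, spacing = spacing), class = "lesion_mask")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing %s mm, gray [%d, %d]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Read a co-registered volume/mask pair
#'
#' Reads a gray-level ultrasound volume and its binary lesion mask from
#' NIfTI files (`.nii` / `.nii.gz`), validates co-registration (identical
#' shapes), and applies the [lesion_mask()] largest-component rule.
#'
#' @param volume_path,mask_path paths to NIfTI files.
#' @param clip clip out-of-range gray values instead of erroring.
#' @param spacing_override optional numeric length-3 replacing the header
#'   spacing (mm).
#' @return list with elements `volume` ([voxel_volume()]) and `mask`
#'   ([lesion_mask()]).
#' @export
read_case <- function(volume_path, mask_path, clip = FALSE,
                      spacing_override = NULL) {
  vol <- read_nifti_volume(volume_path)
  msk <- read_nifti_volume(mask_path)
  if (!identical(dim(vol$data), dim(msk$data))) {
    stop(sprintf("shape mismatch: volume %s vs mask %s",
                 paste(dim(vol$data), collapse = "x"),
                 paste(dim(msk$data), collapse = "x")), call. = FALSE)
  }
  spacing <- if (is.null(spacing_override)) vol$spacing else
    as.numeric(spacing_override)
  list(volume = voxel_volume(vol$data, spacing, clip = clip),
       mask = lesion_mask(msk$data, spacing))
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unsupported volume format (expected .nii or .nii.gz): ", path,
         call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  a <- array(as.vector(a), dim(a))   # drop niftiImage attributes
  if (length(dim(a)) == 4 && dim(a)[4] == 1) a <- a[, , , 1]
  if (length(dim(a)) != 3) {
    stop("expected a rank-3 image, got rank ", length(dim(a)), call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  list(data = a, spacing = as.numeric(sp))
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [voxel_volume()] or [lesion_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "voxel_volume") || inherits(x, "lesion_mask"))
  data <- if (inherits(x, "lesion_mask")) array(as.integer(x$data), dim(x$data))
          else x$data
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume/mask pair to isotropic voxels
#'
#' Optional preprocessing for anisotropic acquisitions: nearest-neighbour
#' resampling onto an isotropic lattice at the requested spacing (default:
#' the finest of the three input spacings). Texture displacements are
#' defined on the voxel lattice, so resampling changes them; it is off by
#' default and exposed as an explicit choice.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [lesion_mask()] (optional).
#' @param target_spacing isotropic spacing in mm.
#' @return list with resampled `volume` and `mask` (NULL if not supplied).
#' @export
resample_isotropic <- function(volume, mask = NULL,
                               target_spacing = min(volume$spacing)) {
  sp <- volume$spacing
  d <- dim(volume$data)
  newd <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  idx <- lapply(1:3, function(ax) {
    src <- ((seq_len(newd[ax]) - 0.5) * target_spacing) / sp[ax] + 0.5
    pmin(pmax(as.integer(round(src)), 1L), d[ax])
  })
  vdata <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out <- list(volume = voxel_volume(vdata, rep(target_spacing, 3)), mask = NULL)
  if (!is.null(mask)) {
    mdata <- mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out$mask <- lesion_mask(mdata, rep(target_spacing, 3))
  }
  out
}

#' Write a feature table to CSV
#'
#' One row per case: `case_id`, the 44 features in canonical (report) order,
#' and optionally `label`. Values are written with 17 significant digits so
#' the table round-trips losslessly through [read_feature_table()].
#'
#' @param features numeric matrix or data frame whose columns are the 44
#'   features named as in [feature_names()]; row order = case order.
#' @param case_ids character vector of case identifiers.
#' @param labels optional vector of grade labels ("low"/"high").
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, case_ids, path, labels = NULL) {
  fn <- feature_names()
  features <- as.data.frame(features, check.names = FALSE, optional = TRUE)
  if (nrow(features) > 0 || ncol(features) > 0) {
    if (!identical(colnames(features), fn)) {
      if (!all(fn %in% colnames(features))) {
        stop("partial feature vector: missing ",
             paste(setdiff(fn, colnames(features)), collapse = ", "),
             call. = FALSE)
      }
      features <- features[, fn, drop = FALSE]
    }
  } else {
    features <- as.data.frame(matrix(numeric(0), 0, length(fn),
                                     dimnames = list(NULL, fn)),
                              check.names = FALSE)
  }
  stopifnot(length(case_ids) == nrow(features))
  fmt <- vapply(features, function(col) sprintf("%.17g", as.numeric(col)),
                character(nrow(features)))
  if (nrow(features) == 1L) fmt <- matrix(fmt, nrow = 1L)
  if (nrow(features) == 0L) fmt <- matrix(character(0), 0, length(fn))
  out <- data.frame(case_id = as.character(case_ids), fmt,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("case_id", fn)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(features))
    out$label <- as.character(labels)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data frame with `case_id`, the 44 feature columns (numeric) and,
#'   if present, `label`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fn <- feature_names()
  missing <- setdiff(fn, colnames(df))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in fn) df[[nm]] <- as.numeric(df[[nm]])
  df
}
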