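# Lesion-mask arithmetic: ROI overlap percentages, infarct volume, and the
# exclusion flags used in the lesion-excluded secondary analysis.

#' Construct a binary volume mask
#'
#' A 3D binary grid with a voxel size (mm per axis) and a space tag; masks
#' are only comparable when their shapes, voxel sizes and space tags match
#' (registration is assumed to have happened upstream).
#'
#' @param grid 3D array of 0/1 (or logical)
#' @param voxel_size_mm length-3 numeric, mm per axis (default c(1,1,1))
#' @param space_tag text label of the coordinate space (default "MNI")
#' @return object of class `fpcoh_mask`
#' @export
volume_mask <- function(grid, voxel_size_mm = c(1, 1, 1), space_tag = "MNI") {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3) stop("mask grid must be a 3D array")
  vals <- unique(as.vector(grid))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary (0/1)")
  storage.mode(grid) <- "integer"
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  structure(list(grid = grid, voxel_size_mm = as.numeric(voxel_size_mm),
                 space_tag = space_tag),
            class = "fpcoh_mask")
}

#' Read / write a volume mask as NIfTI
#' @param path NIfTI file path
#' @param space_tag space label to attach (default "MNI")
#' @return `fpcoh_mask`
#' @export
read_mask_nifti <- function(path, space_tag = "MNI") {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  volume_mask((as.array(img) != 0) * 1L, voxel_size_mm = vox,
              space_tag = space_tag)
}

#' @rdname read_mask_nifti
#' @param mask `fpcoh_mask`
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(mask$grid)
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_compatible_masks <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("mask grids have different shapes")
  if (!isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)))
    stop("mask voxel sizes differ")
  if (!identical(a$space_tag, b$space_tag))
    stop("mask space tags differ ('", a$space_tag, "' vs '", b$space_tag, "')")
}

#' Percent of an ROI overlapped by a lesion
#'
#' `100 * |lesion AND roi| / |roi|`: the fraction of ROI voxels that fall
#' inside the lesion, in percent. Note the denominator is the second
#' argument; swapping arguments changes only the normalization.
#'
#' @param lesion,roi compatible `fpcoh_mask` objects
#' @return percent in `[0, 100]`
#' @export
overlap_percent <- function(lesion, roi) {
  check_compatible_masks(lesion, roi)
  n_roi <- sum(roi$grid)
  if (n_roi == 0) stop("ROI mask is empty: overlap undefined")
  100 * sum(lesion$grid & roi$grid) / n_roi
}

#' Infarct volume in cubic centimeters
#' @param lesion `fpcoh_mask`
#' @return volume in cc (voxel count x voxel volume / 1000)
#' @export
infarct_volume <- function(lesion) {
  sum(lesion$grid) * prod(lesion$voxel_size_mm) / 1000
}

#' Per-subject injury profile
#'
#' Computes the lesion's overlap with each named ROI mask, the infarct
#' volume, and the exclusion flag: a subject is excluded from the secondary
#' analysis when the lesion touches any critical ROI (any overlap above
#' `min_overlap_pct`, default 0 so that any nonzero damage excludes).
#'
#' @param lesion `fpcoh_mask`
#' @param roi_masks named list of `fpcoh_mask`
#' @param critical_rois ROI names whose damage forces exclusion (default
#'   all of `roi_masks`)
#' @param min_overlap_pct overlap percentage strictly above which a critical
#'   ROI counts as damaged (default 0)
#' @return list with `overlap_pct` (named), `infarct_volume_cc`, `excluded`
#' @export
injury_profile <- function(lesion, roi_masks,
                           critical_rois = names(roi_masks),
                           min_overlap_pct = 0) {
  if (is.null(names(roi_masks)) || any(names(roi_masks) == ""))
    stop("roi_masks must be a named list")
  ov <- vapply(roi_masks, function(r) overlap_percent(lesion, r), numeric(1))
  miss <- setdiff(critical_rois, names(ov))
  if (length(miss))
    stop("no overlap entry for critical ROI: ", paste(miss, collapse = ", "))
  list(overlap_pct = ov,
       infarct_volume_cc = infarct_volume(lesion),
       excluded = any(ov[critical_rois] > min_overlap_pct))
}

#' Exclusion flags for a cohort of injury profiles
#'
#' @param profiles named list of injury profiles (as from
#'   [injury_profile()]), one per subject
#' @param critical_rois ROI names checked for damage
#' @param min_overlap_pct threshold as in [injury_profile()]
#' @return named logical vector, TRUE = excluded
#' @export
exclusion_flags <- function(profiles, critical_rois,
                            min_overlap_pct = 0) {
  vapply(profiles, function(p) {
    miss <- setdiff(critical_rois, names(p$overlap_pct))
    if (length(miss))
      stop("profile missing overlap for: ", paste(miss, collapse = ", "))
    any(p$overlap_pct[critical_rois] > min_overlap_pct)
  }, logical(1))
}
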