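#' Area-weighted volume-of-interest mean
#'
#' Aggregates per-slice region-of-interest (ROI) means into the per-patient
#' volume-of-interest (VOI) value as sum(A_i V_i) / sum(A_i), where A_i is
#' the ROI area on slice i and V_i the mean parameter value inside that
#' ROI. The result is invariant to slice ordering and to any uniform
#' rescaling of the areas, so it does not matter whether areas are physical
#' (mm^2) or plain voxel counts, as long as they are consistent.
#'
#' @param slices Data frame with columns `area` (> 0) and `mean_value`
#'   (one row per tumor-bearing slice), as returned by
#'   [extract_roi_means()].
#' @return List with `value` (the area-weighted mean) and `n_slices`.
#' @examples
#' voi_weighted_mean(data.frame(area = c(2, 3), mean_value = c(10, 20)))$value  # 16
#' @export
voi_weighted_mean <- function(slices) {
  if (!is.data.frame(slices) || nrow(slices) == 0)
    stopf("need at least one ROI slice")
  if (!all(c("area", "mean_value") %in% names(slices)))
    stopf("slices must have columns 'area' and 'mean_value'")
  a <- slices$area; v <- slices$mean_value
  if (any(!is.finite(a)) || any(a <= 0)) stopf("all areas must be > 0")
  if (any(!is.finite(v))) stopf("all slice means must be finite")
  list(value = sum(a * v) / sum(a), n_slices = nrow(slices))
}

#' Per-slice ROI means from a parameter map
#'
#' Reduces a 3-D parameter map under a tumor mask to one row per
#' mask-positive slice: the ROI area (count of non-missing masked voxels
#' times the in-plane voxel area) and the mean parameter value over the
#' non-missing masked voxels. Missing voxels (unfittable fits) contribute
#' to neither the area nor the mean, mirroring the exclusion of necrotic
#' or cystic regions from manual ROIs. Slices where every masked voxel is
#' missing are dropped with a warning.
#'
#' @param map 3-D numeric array (a parameter map; NA = missing).
#' @param mask 3-D array congruent with `map`; voxels with `mask > 0`
#'   belong to the ROI.
#' @param pixdim In-plane voxel dimensions (length 2), arbitrary but
#'   consistent units. Default `c(1, 1)` gives areas in voxel counts.
#' @return Data frame with columns `slice_index` (1-based along the third
#'   axis), `area` and `mean_value`.
#' @export
extract_roi_means <- function(map, mask, pixdim = c(1, 1)) {
  if (!identical(dim(map), dim(mask))) stopf("map and mask grids differ")
  if (length(dim(map)) != 3) stopf("map must be a 3-D array")
  voxel_area <- prod(pixdim[1:2])
  out <- lapply(seq_len(dim(map)[3]), function(k) {
    in_roi <- mask[, , k] > 0
    if (!any(in_roi)) return(NULL)
    vox <- map[, , k][in_roi]
    ok <- is.finite(vox)
    if (!any(ok)) {
      warning(sprintf("slice %d: all ROI voxels missing; dropped", k))
      return(NULL)
    }
    data.frame(slice_index = k, area = sum(ok) * voxel_area,
               mean_value = mean(vox[ok]))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE))) %||%
    data.frame(slice_index = integer(), area = numeric(),
               mean_value = numeric())
}

#' VOI summary of a parameter map under a mask
#'
#' Convenience wrapper: [extract_roi_means()] followed by
#' [voi_weighted_mean()].
#'
#' @inheritParams extract_roi_means
#' @return List with `value` and `n_slices`.
#' @export
voi_from_map <- function(map, mask, pixdim = c(1, 1)) {
  voi_weighted_mean(extract_roi_means(map, mask, pixdim))
}
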