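## Airway volume and minimal cross-sectional area -----------------------------

#' Axial bounding planes of the upper airway
#'
#' The superior boundary is the axial plane through the hard palate (PNS
#' and ANS), parallel to the Frankfort plane; since two jittered points
#' rarely share a z-value exactly, the mean of their z-coordinates is used
#' and a warning is emitted when they disagree by more than 3 mm. The
#' inferior boundary is the axial plane through the anterior point of the
#' third cervical vertebra (C3).
#'
#' @param lms A reoriented `landmark_set` with PNS, ANS and C3.
#' @return Named numeric vector `c(z_sup, z_inf)` in mm, `z_sup > z_inf`.
#' @export
bounding_planes <- function(lms) {
  stopifnot(inherits(lms, "landmark_set"))
  check_reoriented(lms)
  require_landmarks(lms, c("PNS", "ANS", "C3"))
  z_pns <- landmark(lms, "PNS")[3]
  z_ans <- landmark(lms, "ANS")[3]
  if (abs(z_pns - z_ans) > 3)
    warning(sprintf(
      "PNS and ANS differ by %.1f mm in z; palatal plane poorly horizontal",
      abs(z_pns - z_ans)))
  z_sup <- (z_pns + z_ans) / 2
  z_inf <- landmark(lms, "C3")[3]
  if (z_sup <= z_inf)
    stop("superior bounding plane is not above the inferior one")
  c(z_sup = unname(z_sup), z_inf = unname(z_inf))
}

#' Crop a grid between two axial planes
#'
#' Voxels whose centers have z in `[z_inf, z_sup]` (both ends inclusive)
#' are retained; all others are cleared. The grid extent is unchanged.
#'
#' @param grid A `voxel_grid`.
#' @param z_sup,z_inf Plane heights in mm, `z_sup > z_inf`.
#' @return A `voxel_grid`.
#' @export
crop_between_planes <- function(grid, z_sup, z_inf) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (z_sup <= z_inf) stop("z_sup must exceed z_inf")
  zc <- grid_extent(grid)$z
  keep <- zc >= z_inf & zc <= z_sup
  if (!any(keep))
    stop("bounding planes do not intersect the grid extent")
  mask <- grid$mask
  mask[, , !keep] <- FALSE
  voxel_grid(mask, grid$voxel, grid$origin, grid$frame)
}

#' Airway volume of a binary grid
#'
#' @param grid A `voxel_grid`.
#' @return Volume in mm^3: (number of air voxels) x voxel^3.
#' @export
airway_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  sum(grid$mask) * grid$voxel^3
}

#' Minimal axial cross-sectional area and its extents
#'
#' Per axial slice, area = (air voxels) x voxel^2; the minimal
#' cross-sectional area (CSAmin) is the minimum over slices containing any
#' air, ties broken toward the most inferior slice. `Ap` and `Lat` are the
#' anteroposterior (x) and lateral (y) bounding-box extents of the air
#' voxels in the minimal slice, measured voxel-center to voxel-center plus
#' one voxel.
#'
#' @param grid A non-empty `voxel_grid` (already cropped to the airway).
#' @return Named list: `CSAmin` (mm^2), `slice_z` (mm), `Ap` (mm),
#'   `Lat` (mm).
#' @export
csa_min <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  counts <- apply(grid$mask, 3, sum)
  nz <- which(counts > 0)
  if (length(nz) == 0L) stop("grid contains no air voxels")
  areas <- counts[nz] * grid$voxel^2
  k <- nz[which.min(areas)]           # which.min returns the first (most
                                      # inferior) slice among ties
  sl <- grid$mask[, , k]
  ij <- which(sl, arr.ind = TRUE)
  ap <- (diff(range(ij[, 1])) + 1L) * grid$voxel
  lat <- (diff(range(ij[, 2])) + 1L) * grid$voxel
  list(CSAmin = min(areas),
       slice_z = grid_extent(grid)$z[k],
       Ap = ap, Lat = lat)
}

#' Full airway metric extraction
#'
#' Convenience wrapper: optionally keeps only the largest 26-connected
#' component, crops the grid between the palatal (PNS/ANS) and C3 planes
#' derived from the subject's landmarks, and extracts volume and
#' minimal-slice metrics.
#'
#' @param grid A reoriented `voxel_grid`.
#' @param lms The subject's reoriented `landmark_set`.
#' @param component_filter Apply [largest_component()] first (default TRUE).
#' @return Named numeric vector: `Vol` (mm^3), `CSAmin` (mm^2), `Ap` (mm),
#'   `Lat` (mm), `slice_z` (mm).
#' @export
airway_metrics <- function(grid, lms, component_filter = TRUE) {
  if (component_filter) grid <- largest_component(grid)
  zb <- bounding_planes(lms)
  cropped <- crop_between_planes(grid, zb["z_sup"], zb["z_inf"])
  cs <- csa_min(cropped)
  c(Vol = airway_volume(cropped), CSAmin = cs$CSAmin,
    Ap = cs$Ap, Lat = cs$Lat, slice_z = cs$slice_z)
}
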