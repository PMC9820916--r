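## Anatomical reference planes and rigid reorientation ------------------------

#' Fit a plane through three points
#'
#' The plane normal follows the right-hand rule on (p2 - p1, p3 - p1) and is
#' returned as a unit vector; `offset` is the signed distance of the plane
#' from the origin, so a point p lies on the plane iff dot(normal, p) = offset.
#'
#' @param p1,p2,p3 Numeric length-3 points in mm.
#' @return An object of class `amorph_plane` with fields `normal`, `offset`,
#'   `points`.
#' @examples
#' fit_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # the z = 0 plane
#' @export
fit_plane <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 3, length(p2) == 3, length(p3) == 3)
  n <- cross3(p2 - p1, p3 - p1)
  area2 <- sqrt(sum(n^2))          # twice the triangle area
  if (area2 / 2 <= 1e-6)
    stop("degenerate plane: the three points are (near-)collinear")
  n <- n / area2
  structure(list(normal = n, offset = sum(n * p1),
                 points = rbind(p1, p2, p3)),
            class = "amorph_plane")
}

#' @export
print.amorph_plane <- function(x, ...) {
  cat(sprintf("<plane> normal = (%.4f, %.4f, %.4f), offset = %.3f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a rigid transform
#'
#' A rigid (proper) transform x -> R x + t. The rotation must be orthonormal
#' with determinant +1; reflections are rejected.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("improper rotation (reflection) not allowed")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = ", "), "mm\n")
  invisible(x)
}

#' Invert or compose rigid transforms
#'
#' @param t,t1,t2 `rigid_transform` objects.
#' @return A `rigid_transform`. `compose_transform(t1, t2)` applies `t2`
#'   first, then `t1`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% t$translation))
}

#' @rdname invert_transform
#' @export
compose_transform <- function(t1, t2) {
  rigid_transform(t1$rotation %*% t2$rotation,
                  as.numeric(t1$rotation %*% t2$translation) + t1$translation)
}

## rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b)
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis orthogonal to a
    axis <- cross3(a, c(1, 0, 0))
    if (sqrt(sum(axis^2)) < 1e-6) axis <- cross3(a, c(0, 1, 0))
    axis <- axis / sqrt(sum(axis^2))
    K <- skew3(axis)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew3(v / s)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Compute the reorientation transform for a subject
#'
#' Finds the rigid transform that brings a subject into the canonical
#' anatomical frame, emulating the two-step reorientation used in
#' craniofacial CBCT workflows:
#'
#' 1. The Frankfort horizontal (FH) plane, fit through rPo, rOr and lOr, is
#'    rotated to be horizontal, with its normal pointing superiorly (toward
#'    the side of the cranial landmarks), so the three FH landmarks share
#'    one z-value.
#' 2. A rotation about the (now vertical) Z axis aligns the horizontal
#'    component of the midsagittal-plane normal (plane through Na, ANS,
#'    MGNM) with the Y axis, leaving the FH alignment intact; the direction
#'    is chosen so +X points anteriorly (from MGNM toward Na).
#'
#' Finally the origin is moved to Sella (S). After FH alignment the three
#' midsagittal landmarks need not be exactly coplanar with a vertical
#' plane; only the horizontal component of their plane normal is aligned
#' and the residual |y| of Na, ANS, MGNM is returned as a QC metric.
#'
#' @param lms A `landmark_set` containing at least rPo, rOr, lOr, Na, ANS,
#'   MGNM and S.
#' @return A `rigid_transform` with attribute `"midsagittal_residual_mm"`
#'   (max |y| of Na, ANS, MGNM after reorientation).
#' @export
compute_reorientation <- function(lms) {
  stopifnot(inherits(lms, "landmark_set"))
  require_landmarks(lms, c("rPo", "rOr", "lOr", "Na", "ANS", "MGNM", "S"))

  fh <- fit_plane(landmark(lms, "rPo"), landmark(lms, "rOr"),
                  landmark(lms, "lOr"))
  ms <- fit_plane(landmark(lms, "Na"), landmark(lms, "ANS"),
                  landmark(lms, "MGNM"))
  ang <- acos(min(1, abs(sum(fh$normal * ms$normal)))) * 180 / pi
  if (ang < 10)
    stop("Frankfort and midsagittal planes are near-parallel (< 10 degrees)")

  # orient the FH normal superiorly: Na lies above the FH plane
  n_fh <- fh$normal
  if (sum(n_fh * (landmark(lms, "Na") - landmark(lms, "rPo"))) < 0)
    n_fh <- -n_fh
  R1 <- rotation_between(n_fh, c(0, 0, 1))

  # midsagittal normal after FH alignment; align horizontal part to +/-Y
  n_ms <- as.numeric(R1 %*% ms$normal)
  h <- c(n_ms[1], n_ms[2], 0)
  hn <- sqrt(sum(h^2))
  if (hn < 1e-9)
    stop("degenerate midsagittal plane after Frankfort alignment")
  theta <- atan2(h[1], h[2])     # rotate h onto +Y
  R <- rot_z(theta) %*% R1

  # +X must point anteriorly (MGNM -> Na)
  ant <- as.numeric(R %*% (landmark(lms, "Na") - landmark(lms, "MGNM")))
  if (ant[1] < 0)
    R <- rot_z(pi) %*% R

  tr <- rigid_transform(R, -as.numeric(R %*% landmark(lms, "S")))

  re <- apply_transform(lms, tr)
  resid <- max(abs(re$coords[c("Na", "ANS", "MGNM"), "y"]))
  attr(tr, "midsagittal_residual_mm") <- resid
  tr
}

#' Apply a rigid transform
#'
#' Landmarks are mapped exactly; voxel grids are resampled onto an
#' axis-aligned grid of the same voxel size by nearest-neighbour lookup
#' (preserving binarity).
#'
#' @param x A `landmark_set` or `voxel_grid`.
#' @param t A `rigid_transform`.
#' @param frame Frame tag given to the result (default `"reoriented"`).
#' @return Object of the same class as `x`.
#' @export
apply_transform <- function(x, t, frame = "reoriented") {
  stopifnot(inherits(t, "rigid_transform"))
  UseMethod("apply_transform")
}

#' @export
apply_transform.landmark_set <- function(x, t, frame = "reoriented") {
  new <- x$coords %*% t(t$rotation) +
    matrix(t$translation, nrow(x$coords), 3, byrow = TRUE)
  rownames(new) <- rownames(x$coords)
  landmark_set(new, frame = frame, subject_id = x$subject_id)
}

#' @export
apply_transform.voxel_grid <- function(x, t, frame = "reoriented") {
  # corners of the input grid, mapped forward, define the output extent
  ext <- grid_extent(x)
  corners <- as.matrix(expand.grid(ext$x, ext$y, ext$z))
  mapped <- corners %*% t(t$rotation) +
    matrix(t$translation, nrow(corners), 3, byrow = TRUE)
  lo <- apply(mapped, 2, min); hi <- apply(mapped, 2, max)
  v <- x$voxel
  dims <- pmax(1L, as.integer(round((hi - lo) / v)) + 1L)
  origin <- lo    # output lattice anchored on the mapped centers
  # inverse-map output voxel centers into the input grid
  inv <- invert_transform(t)
  cx <- origin[1] + (seq_len(dims[1]) - 1) * v
  cy <- origin[2] + (seq_len(dims[2]) - 1) * v
  cz <- origin[3] + (seq_len(dims[3]) - 1) * v
  pts <- as.matrix(expand.grid(cx, cy, cz))
  src <- pts %*% t(inv$rotation) +
    matrix(inv$translation, nrow(pts), 3, byrow = TRUE)
  ijk <- sweep(src, 2, x$origin, "-") / v
  ijk <- round(ijk) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dim(x$mask)[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= dim(x$mask)[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= dim(x$mask)[3]
  vals <- logical(nrow(ijk))
  vals[ok] <- x$mask[cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3])]
  voxel_grid(array(vals, dims), voxel = v, origin = origin, frame = frame)
}

#' Serialize a rigid transform to JSON
#'
#' @param t A `rigid_transform`.
#' @param path Output path.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(
    list(rotation = as.vector(t(t$rotation)),   # row-major
         translation = t$translation,
         convention = "x' = R x + t; +X anterior, +Y left, +Z superior, origin S"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}
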