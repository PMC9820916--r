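## Binary voxel grids ---------------------------------------------------------

#' Construct a binary voxel grid
#'
#' A 3D binary occupancy grid (air = TRUE) on an isotropic lattice. Axis
#' order is (x, y, z) in the reoriented anatomical frame; `origin` is the
#' center of voxel (1, 1, 1) in mm.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param voxel Isotropic voxel edge length in mm (> 0).
#' @param origin Numeric length-3 center of the first voxel, mm.
#' @param frame Frame tag (`"raw"` or `"reoriented"`).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(mask, voxel, origin = c(0, 0, 0),
                       frame = "reoriented") {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  voxel <- as.numeric(voxel)
  if (!is.finite(voxel) || voxel <= 0) stop("voxel size must be > 0 mm")
  structure(list(mask = mask, voxel = voxel, origin = as.numeric(origin),
                 frame = frame),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels @ %.3g mm, %d air, frame = %s\n",
              paste(dim(x$mask), collapse = "x"), x$voxel,
              sum(x$mask), x$frame))
  invisible(x)
}

## voxel-center coordinate vectors along each axis
grid_extent <- function(g) {
  d <- dim(g$mask)
  list(x = g$origin[1] + (seq_len(d[1]) - 1) * g$voxel,
       y = g$origin[2] + (seq_len(d[2]) - 1) * g$voxel,
       z = g$origin[3] + (seq_len(d[3]) - 1) * g$voxel)
}

#' Read / write voxel grids as NIfTI
#'
#' Grids are stored as uint8 NIfTI volumes with isotropic spacing in the
#' header; the origin is carried in the qform translation.
#'
#' @param grid A `voxel_grid`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
write_grid_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$voxel
  img <- RNifti::asNifti(array(as.integer(grid$mask), dim(grid$mask)),
                         reference = list(pixdim = c(-1, v, v, v, 1, 1, 1, 1)),
                         datatype = "uint8")
  xf <- structure(rbind(cbind(diag(3) * v, grid$origin), c(0, 0, 0, 1)),
                  code = 2L)
  RNifti::qform(img) <- xf
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_grid_nifti
#' @param frame Frame tag attached on read.
#' @return `read_grid_nifti()` returns a `voxel_grid`.
#' @export
read_grid_nifti <- function(path, frame = "reoriented") {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  # spacing from the xform column norms (robust to a stale pixdim field)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1])
    stop("grid is not isotropic: spacing = ", paste(sp, collapse = ", "))
  origin <- xf[1:3, 4]
  voxel_grid(array(as.array(img) != 0, dim(img)), voxel = sp[1],
             origin = origin, frame = frame)
}

#' Largest 26-connected component of a binary grid
#'
#' Retains only the largest 26-connected air component, emulating the
#' segmentation of a single airway object and dropping stray voxels.
#' Implemented as a vectorized breadth-first flood fill.
#'
#' @param grid A `voxel_grid`.
#' @return A `voxel_grid` with all but the largest component cleared.
#' @export
largest_component <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$mask)
  n <- prod(d)
  air <- which(grid$mask)
  if (length(air) == 0L) return(grid)

  # 26-neighbourhood linear-index offsets on a padded index space
  dp <- d + 2L
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  offs <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]

  # embed mask into padded space
  idx3 <- arrayInd(air, d)
  pidx <- idx3[, 1] + 1L + idx3[, 2] * dp[1] + idx3[, 3] * dp[1] * dp[2]
  inair <- logical(prod(dp)); inair[pidx] <- TRUE

  unvisited <- inair
  best <- integer(0)
  while (any(unvisited)) {
    seed <- which.max(unvisited)
    comp <- logical(prod(dp))
    frontier <- seed
    comp[seed] <- TRUE; unvisited[seed] <- FALSE
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      nb <- nb[nb >= 1 & nb <= prod(dp)]
      nb <- nb[unvisited[nb]]
      comp[nb] <- TRUE; unvisited[nb] <- FALSE
      frontier <- nb
    }
    if (sum(comp) > length(best)) best <- which(comp)
    if (length(best) >= sum(inair) - length(best)) break  # cannot be beaten
  }

  # map padded linear indices back to original (x, y, z) subscripts
  k <- best - 1L
  z <- k %/% (dp[1] * dp[2]); r <- k %% (dp[1] * dp[2])
  y <- r %/% dp[1]; x <- r %% dp[1]   # x,y,z are original 1-based subscripts
  mask <- array(FALSE, d)
  mask[cbind(x, y, z)] <- TRUE
  voxel_grid(mask, grid$voxel, grid$origin, grid$frame)
}
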