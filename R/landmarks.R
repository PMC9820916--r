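#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Landmark containers -------------------------------------------------------

#' Names of the 25 anatomical landmarks
#'
#' The 24 standard craniofacial landmarks (A, ANS, B, Ba, BEP, C3, H, lCN,
#' lGo, lOr, lTb, MGNM, Me, Na, Pg, PNS, rCN, rGo, rOr, rPo, rTb, S, Tph,
#' TUV) plus `LP`, the most posterior point of the soft-palate contour,
#' which the horizontal soft-palate measure (HSP) requires.
#'
#' @return Character vector of length 25.
#' @export
landmark_names <- function() {
  c("A", "ANS", "B", "Ba", "BEP", "C3", "H", "lCN", "lGo", "lOr", "lTb",
    "MGNM", "Me", "Na", "Pg", "PNS", "rCN", "rGo", "rOr", "rPo", "rTb",
    "S", "Tph", "TUV", "LP")
}

#' Construct a landmark set
#'
#' A landmark set is a named collection of 3D anatomical points, in mm,
#' for one subject, together with a frame tag saying whether the
#' coordinates are raw (scanner frame) or reoriented (Frankfort +
#' midsagittal canonical frame: +X anterior, +Y subject-left, +Z superior,
#' origin at Sella).
#'
#' @param coords Numeric matrix with 3 columns (x, y, z in mm) and one row
#'   per landmark; rownames are landmark names.
#' @param frame `"raw"` or `"reoriented"`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, frame = c("raw", "reoriented"),
                         subject_id = NA_character_) {
  frame <- match.arg(frame)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("landmark coordinates must have 3 columns (x, y, z)")
  if (is.null(rownames(coords)))
    stop("landmark coordinate rows must be named")
  if (anyDuplicated(rownames(coords)))
    stop("duplicated landmark names: ",
         paste(unique(rownames(coords)[duplicated(rownames(coords))]),
               collapse = ", "))
  if (!all(is.finite(coords)))
    stop("landmark coordinates must be finite")
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, frame = frame, subject_id = subject_id),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks, frame = %s%s\n",
              nrow(x$coords), x$frame,
              if (is.na(x$subject_id)) "" else paste0(", subject ", x$subject_id)))
  print(utils::head(round(x$coords, 3)))
  if (nrow(x$coords) > 6L) cat("...\n")
  invisible(x)
}

#' Look up one landmark position
#'
#' @param lms A `landmark_set`.
#' @param name Landmark name.
#' @return Numeric length-3 vector (x, y, z) in mm.
#' @export
landmark <- function(lms, name) {
  stopifnot(inherits(lms, "landmark_set"))
  if (!name %in% rownames(lms$coords))
    stop("missing anatomical landmark: ", name)
  as.numeric(lms$coords[name, ])
}

require_landmarks <- function(lms, names) {
  missing <- setdiff(names, rownames(lms$coords))
  if (length(missing))
    stop("missing anatomical landmark(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

## IO -------------------------------------------------------------------------

#' Read / write landmark tables
#'
#' The on-disk format is a CSV with columns `subject_id`, `landmark`,
#' `x_mm`, `y_mm`, `z_mm`, one row per landmark. `read_landmarks()`
#' returns a named list of `landmark_set` objects (one per subject);
#' `write_landmarks()` serializes a list of them.
#'
#' @param path File path.
#' @param frame Frame tag to attach on read.
#' @return `read_landmarks()`: named list of `landmark_set`.
#' @export
read_landmarks <- function(path, frame = "raw") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "landmark", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(d) {
    m <- as.matrix(d[, c("x_mm", "y_mm", "z_mm")])
    rownames(m) <- d$landmark
    landmark_set(m, frame = frame, subject_id = as.character(d$subject_id[1]))
  })
  out[order(names(out))]
}

#' @param sets List of `landmark_set` objects.
#' @rdname read_landmarks
#' @export
write_landmarks <- function(sets, path) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    id <- if (!is.na(s$subject_id)) s$subject_id else sprintf("S%03d", i)
    data.frame(subject_id = id, landmark = rownames(s$coords),
               x_mm = s$coords[, 1], y_mm = s$coords[, 2], z_mm = s$coords[, 3],
               row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Serialize one landmark set to JSON
#'
#' @param lms A `landmark_set`.
#' @param path Output path.
#' @export
write_landmarks_json <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  obj <- list(subject_id = lms$subject_id, frame = lms$frame,
              landmarks = stats::setNames(
                lapply(rownames(lms$coords),
                       function(n) as.numeric(lms$coords[n, ])),
                rownames(lms$coords)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- do.call(rbind, lapply(obj$landmarks, as.numeric))
  landmark_set(m, frame = obj$frame,
               subject_id = if (is.null(obj$subject_id)) NA_character_
                            else obj$subject_id)
}
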