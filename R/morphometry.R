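## Cephalometric measures -----------------------------------------------------
##
## The measurement panel is the classic soft/hard-tissue description of the
## upper airway region: 19 distances (mm) and 6 angles (degrees) computed
## from the reoriented landmark set, plus age/sex pass-through covariates.

#' Names of the 25 morphometric measures
#'
#' 19 distances (mm) and 6 angles (degrees). `AB_shift`, `HSP` and `VSP`
#' are frame-dependent (defined in the reoriented frame); all others are
#' plain Euclidean distances or vertex angles and therefore rigid-invariant.
#'
#' @return Character vector of length 25.
#' @export
measure_names <- function() {
  c("Me_rGo", "rGo_lGo", "Na_B", "Na_A", "AB_shift", "S_Na", "C3_H",
    "Me_H", "H_PNS", "S_H", "rTb_lTb", "rCN_lCN", "Na_ANS", "BEP_A",
    "BEP_TUV", "HSP", "PNS_TUV", "Ba_Tph", "VSP",
    "SNA", "SNB", "facial_angle", "FMA", "H_S_Ba", "H_Na_S")
}

#' Euclidean distance between two points
#'
#' @param a,b Numeric length-3 points in mm.
#' @return Distance in mm.
#' @export
point_distance <- function(a, b) {
  d <- as.numeric(a) - as.numeric(b)
  sqrt(sum(d * d))
}

#' Angle at a vertex
#'
#' The angle, in degrees, between the arms v->a and v->b.
#'
#' @param a,v,b Numeric length-3 points; `v` is the vertex.
#' @return Angle in degrees, in \[0, 180\].
#' @export
vertex_angle <- function(a, v, b) {
  u <- as.numeric(a) - as.numeric(v)
  w <- as.numeric(b) - as.numeric(v)
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-12 || nw < 1e-12)
    stop("vertex angle undefined: zero-length arm")
  acos(max(-1, min(1, sum(u * w) / (nu * nw)))) * 180 / pi
}

check_reoriented <- function(lms) {
  if (!identical(lms$frame, "reoriented"))
    stop("this measure is defined in the reoriented frame; ",
         "call compute_reorientation()/apply_transform() first")
  invisible(TRUE)
}

#' Signed anteroposterior shift between the maxillary and mandibular points
#'
#' The anteroposterior (x) component of the difference between the A and B
#' points after projection onto the Frankfort plane: positive when A is
#' anterior to B, negative for a protrusive mandible. The signed component
#' (not an unsigned 2D distance) is used so that mandibular protrusion is
#' representable.
#'
#' @param A,B Numeric length-3 points in the reoriented frame.
#' @param lms Optional `landmark_set` used only to check the frame tag.
#' @return Signed shift in mm.
#' @export
ap_shift <- function(A, B, lms = NULL) {
  if (!is.null(lms)) check_reoriented(lms)
  as.numeric(A)[1] - as.numeric(B)[1]
}

#' Horizontal soft-palate measure (HSP)
#'
#' Anteroposterior offset from the posterior nasal spine to the vertical
#' line through the most posterior point of the soft-palate contour (LP):
#' `|x_PNS - x_LP|` in the reoriented frame.
#'
#' @param PNS,LP Numeric length-3 points in the reoriented frame.
#' @param lms Optional `landmark_set` used only to check the frame tag.
#' @return Offset in mm.
#' @export
horizontal_offset <- function(PNS, LP, lms = NULL) {
  if (!is.null(lms)) check_reoriented(lms)
  abs(as.numeric(PNS)[1] - as.numeric(LP)[1])
}

#' Vertical soft-palate measure (VSP)
#'
#' Vertical offset from the horizontal line through the posterior nasal
#' spine to the tip of the soft palate (uvula tip, TUV):
#' `|z_PNS - z_TUV|` in the reoriented frame.
#'
#' @param PNS,TUV Numeric length-3 points in the reoriented frame.
#' @param lms Optional `landmark_set` used only to check the frame tag.
#' @return Offset in mm.
#' @export
vertical_offset <- function(PNS, TUV, lms = NULL) {
  if (!is.null(lms)) check_reoriented(lms)
  abs(as.numeric(PNS)[3] - as.numeric(TUV)[3])
}

#' Frankfort-mandibular plane angle (FMA)
#'
#' Angle between the Frankfort line (rPo-rOr) and the mandibular line
#' (Me-rGo), both projected onto the midsagittal (XZ) plane, as read on a
#' lateral cephalometric view. Reported in (0, 90\].
#'
#' @param rPo,rOr,Me,rGo Numeric length-3 points in the reoriented frame.
#' @param lms Optional `landmark_set` used only to check the frame tag.
#' @return Angle in degrees.
#' @export
fma_angle <- function(rPo, rOr, Me, rGo, lms = NULL) {
  if (!is.null(lms)) check_reoriented(lms)
  u <- as.numeric(rOr) - as.numeric(rPo)
  w <- as.numeric(rGo) - as.numeric(Me)
  u <- c(u[1], u[3]); w <- c(w[1], w[3])   # sagittal projections
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-9 || nw < 1e-9)
    stop("FMA undefined: degenerate sagittal projection")
  a <- acos(max(-1, min(1, abs(sum(u * w)) / (nu * nw)))) * 180 / pi
  a
}

#' Compute the full morphometric measurement vector
#'
#' Evaluates the 19 distances and 6 angles from a reoriented landmark set.
#' A missing landmark raises an error naming the absent point, mirroring
#' the usual non-inclusion rule for incomplete exams; alternatively, with
#' `allow_missing = TRUE`, measures depending on an absent landmark are
#' returned as `NA` (degraded mode, e.g. when LP was not annotated).
#'
#' @param lms A reoriented `landmark_set`.
#' @param age,sex Optional covariates passed through into the result.
#' @param allow_missing If `TRUE`, measures with absent landmarks become `NA`.
#' @return Named numeric vector: 25 measures plus `age` and `sex`
#'   (sex coded 0 = male, 1 = female; `NA` when not given).
#' @export
compute_measures <- function(lms, age = NA_real_, sex = NA_real_,
                             allow_missing = FALSE) {
  stopifnot(inherits(lms, "landmark_set"))
  check_reoriented(lms)
  L <- function(n) landmark(lms, n)

  defs <- list(
    Me_rGo  = function() point_distance(L("Me"), L("rGo")),
    rGo_lGo = function() point_distance(L("rGo"), L("lGo")),
    Na_B    = function() point_distance(L("Na"), L("B")),
    Na_A    = function() point_distance(L("Na"), L("A")),
    AB_shift = function() ap_shift(L("A"), L("B")),
    S_Na    = function() point_distance(L("S"), L("Na")),
    C3_H    = function() point_distance(L("C3"), L("H")),
    Me_H    = function() point_distance(L("Me"), L("H")),
    H_PNS   = function() point_distance(L("H"), L("PNS")),
    S_H     = function() point_distance(L("S"), L("H")),
    rTb_lTb = function() point_distance(L("rTb"), L("lTb")),
    rCN_lCN = function() point_distance(L("rCN"), L("lCN")),
    Na_ANS  = function() point_distance(L("Na"), L("ANS")),
    BEP_A   = function() point_distance(L("BEP"), L("A")),
    BEP_TUV = function() point_distance(L("BEP"), L("TUV")),
    HSP     = function() horizontal_offset(L("PNS"), L("LP")),
    PNS_TUV = function() point_distance(L("PNS"), L("TUV")),
    Ba_Tph  = function() point_distance(L("Ba"), L("Tph")),
    VSP     = function() vertical_offset(L("PNS"), L("TUV")),
    SNA     = function() vertex_angle(L("S"), L("Na"), L("A")),
    SNB     = function() vertex_angle(L("S"), L("Na"), L("B")),
    facial_angle = function() vertex_angle(L("S"), L("Na"), L("Pg")),
    FMA     = function() fma_angle(L("rPo"), L("rOr"), L("Me"), L("rGo")),
    H_S_Ba  = function() vertex_angle(L("H"), L("S"), L("Ba")),
    H_Na_S  = function() vertex_angle(L("H"), L("Na"), L("S")))

  vals <- vapply(measure_names(), function(nm) {
    if (allow_missing) {
      tryCatch(defs[[nm]](), error = function(e) {
        if (grepl("missing anatomical landmark", conditionMessage(e)))
          NA_real_
        else stop(e)
      })
    } else defs[[nm]]()
  }, numeric(1))

  c(vals, age = as.numeric(age), sex = as.numeric(sex))
}

#' Measurement table for a list of subjects
#'
#' @param sets Named list of reoriented `landmark_set` objects.
#' @param age,sex Optional numeric vectors (recycled NA otherwise).
#' @param allow_missing Passed to [compute_measures()].
#' @return Data frame, one row per subject, columns `subject_id`, the 25
#'   measures, `age`, `sex`.
#' @export
measure_table <- function(sets, age = NULL, sex = NULL,
                          allow_missing = FALSE) {
  n <- length(sets)
  if (is.null(age)) age <- rep(NA_real_, n)
  if (is.null(sex)) sex <- rep(NA_real_, n)
  rows <- lapply(seq_len(n), function(i)
    compute_measures(sets[[i]], age = age[i], sex = sex[i],
                     allow_missing = allow_missing))
  df <- as.data.frame(do.call(rbind, rows))
  ids <- names(sets)
  if (is.null(ids))
    ids <- vapply(sets, function(s)
      if (is.na(s$subject_id)) NA_character_ else s$subject_id, character(1))
  if (anyNA(ids)) ids <- sprintf("S%03d", seq_len(n))
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), df)
}
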