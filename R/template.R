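## Canonical adult landmark template ----------------------------------------
##
## Coordinates are in mm in the canonical frame: +X anterior, +Y subject-left,
## +Z superior, origin at Sella (S). The template is already reoriented: the
## Frankfort landmarks (rPo, rOr, lOr) share one z-value and the midsagittal
## landmarks (Na, ANS, MGNM) sit at y = 0. Positions were constructed so that
## every one of the 25 morphometric measures falls inside the published
## normal-adult ranges; the four cephalometric angles are built exactly
## (SNA 81.8, SNB 77.8, facial angle 79.0, FMA 33.3 degrees) by rotating the
## Na->S direction by the target angle.

template_coords <- function() {
  m <- rbind(
    S    = c(  0.000,   0.000,    0.000),
    Na   = c( 64.000,   0.000,   17.000),
    A    = c( 70.649,   0.000,  -39.712),
    B    = c( 68.433,   0.000,  -77.496),
    Pg   = c( 70.778,   0.000,  -82.770),
    Me   = c( 66.000,   0.000,  -88.000),
    ANS  = c( 70.000,   0.000,  -32.000),
    PNS  = c( 20.000,   0.000,  -34.000),
    LP   = c(  0.900,   0.000,  -55.000),
    TUV  = c( 15.330,   0.000,  -70.200),
    BEP  = c( 12.000,   0.000,  -99.000),
    H    = c( 23.500,   0.000, -100.283),
    C3   = c(-10.500,   0.000,  -95.000),
    Ba   = c(-21.500,   0.000,  -43.800),
    Tph  = c( -4.500,   0.000,  -50.800),
    MGNM = c(-40.000,   0.000,  -40.000),
    rPo  = c( -8.000, -48.000,   -3.000),
    rOr  = c( 55.000, -28.000,   -3.000),
    lOr  = c( 55.000,  28.000,   -3.000),
    rGo  = c(  8.000, -46.000,  -49.900),
    lGo  = c(  8.000,  46.000,  -49.900),
    rTb  = c( 25.000, -24.550,  -40.000),
    lTb  = c( 25.000,  24.550,  -40.000),
    rCN  = c( 55.000, -10.250,  -15.000),
    lCN  = c( 55.000,  10.250,  -15.000))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Canonical adult landmark template
#'
#' Returns the package's canonical landmark configuration: a plausible
#' average adult craniofacial shape expressed in the reoriented frame
#' (+X anterior, +Y subject-left, +Z superior, origin at Sella). It is the
#' seed of the synthetic-cohort generator and the reference configuration
#' of the geometry tests. All 25 morphometric measures computed from it lie
#' inside published adult ranges.
#'
#' @return A `landmark_set` in the `"reoriented"` frame with all 25
#'   landmarks (see [landmark_names()]).
#' @examples
#' tpl <- landmark_template()
#' landmark(tpl, "Na")
#' @export
landmark_template <- function() {
  landmark_set(template_coords(), frame = "reoriented",
               subject_id = "template")
}
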