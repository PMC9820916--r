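# shared helpers: random rigid transforms and brute-force geometry oracles

random_rigid <- function(max_rot_deg = 180, max_trans = 50) {
  ang <- stats::runif(3, -max_rot_deg, max_rot_deg) * pi / 180
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rigid_transform(Rx %*% Ry %*% Rz, stats::runif(3, -max_trans, max_trans))
}

# independent brute-force oracle for the full measurement panel, written
# directly from the coordinate table (no package geometry helpers)
oracle_measures <- function(coords) {
  p <- function(n) as.numeric(coords[n, ])
  d <- function(a, b) {
    dx <- p(a) - p(b)
    (dx[1]^2 + dx[2]^2 + dx[3]^2)^0.5
  }
  ang <- function(a, v, b) {
    u <- p(a) - p(v); w <- p(b) - p(v)
    cu <- sum(u * w) / ((sum(u^2) * sum(w^2))^0.5)
    atan2(sqrt(max(0, 1 - cu^2)), cu) * 180 / pi
  }
  fma <- function() {
    u <- p("rOr") - p("rPo"); w <- p("rGo") - p("Me")
    u <- u[c(1, 3)]; w <- w[c(1, 3)]
    cu <- abs(sum(u * w)) / ((sum(u^2) * sum(w^2))^0.5)
    atan2(sqrt(max(0, 1 - cu^2)), cu) * 180 / pi
  }
  c(Me_rGo = d("Me", "rGo"), rGo_lGo = d("rGo", "lGo"),
    Na_B = d("Na", "B"), Na_A = d("Na", "A"),
    AB_shift = p("A")[1] - p("B")[1],
    S_Na = d("S", "Na"), C3_H = d("C3", "H"), Me_H = d("Me", "H"),
    H_PNS = d("H", "PNS"), S_H = d("S", "H"),
    rTb_lTb = d("rTb", "lTb"), rCN_lCN = d("rCN", "lCN"),
    Na_ANS = d("Na", "ANS"), BEP_A = d("BEP", "A"),
    BEP_TUV = d("BEP", "TUV"),
    HSP = abs(p("PNS")[1] - p("LP")[1]),
    PNS_TUV = d("PNS", "TUV"), Ba_Tph = d("Ba", "Tph"),
    VSP = abs(p("PNS")[3] - p("TUV")[3]),
    SNA = ang("S", "Na", "A"), SNB = ang("S", "Na", "B"),
    facial_angle = ang("S", "Na", "Pg"), FMA = fma(),
    H_S_Ba = ang("H", "S", "Ba"), H_Na_S = ang("H", "Na", "S"))
}

# published adult ranges (min, max) for the 25 measures and airway metrics
published_ranges <- function() {
  rbind(
    Me_rGo = c(57.5, 95.8), rGo_lGo = c(78.8, 107), Na_B = c(77.1, 118),
    Na_A = c(47.3, 67.0), AB_shift = c(-12.1, 13.9), S_Na = c(58.6, 77.9),
    C3_H = c(25.8, 45.2), Me_H = c(27.7, 51.7), H_PNS = c(44.2, 76.0),
    S_H = c(77.9, 122), rTb_lTb = c(41.7, 58.3), rCN_lCN = c(12.9, 54.4),
    Na_ANS = c(42.2, 60.5), BEP_A = c(75.0, 102), BEP_TUV = c(15.5, 43.8),
    HSP = c(11.1, 34.9), PNS_TUV = c(27.1, 44.9), Ba_Tph = c(11.3, 38.9),
    VSP = c(26.6, 49.0), SNA = c(72.8, 92.2), SNB = c(66.6, 96.5),
    facial_angle = c(68.7, 93.4), FMA = c(18.2, 48.1),
    H_S_Ba = c(25.6, 54.7), H_Na_S = c(46.8, 68.6),
    age = c(22, 72), Vol = c(1614, 40720), CSAmin = c(46, 618))
}

# small synthetic landmark set with only the named points, for plane tests
tiny_landmarks <- function(pts, frame = "raw") {
  m <- do.call(rbind, pts)
  rownames(m) <- names(pts)
  landmark_set(m, frame = frame)
}
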