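## Classical statistics: descriptives, Kendall tau-b, ICC, PCA ---------------

#' Descriptive summary of a measurement table
#'
#' Mean, SD, median, quartiles, min and max per numeric variable, plus a
#' Shapiro-Wilk normality flag at the 5% level (quartiles are the primary
#' location/scale summary for the many non-normal airway measures).
#'
#' @param table Data frame; non-numeric columns are ignored.
#' @return Data frame with one row per variable: `variable`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `min`, `max`, `shapiro_p`, `normal`.
#' @export
describe_measures <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 2) stop("need at least 2 rows to describe")
  out <- lapply(names(num), function(v) {
    x <- num[[v]]
    x <- x[!is.na(x)]
    sw <- if (length(unique(x)) > 2 && length(x) >= 3 && length(x) <= 5000)
      tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)),
               min = min(x), max = max(x),
               shapiro_p = sw, normal = !is.na(sw) && sw >= 0.05)
  })
  do.call(rbind, out)
}

#' Kendall's tau-b with tie correction
#'
#' Pairwise concordance statistic with the tie-corrected (tau-b)
#' denominator, and a p-value from the normal approximation of the
#' concordance score S with tie-corrected variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `tau`, `p`, `n`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Kendall's tau undefined")

  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  # tie-corrected variance of S (as in the classical large-sample test)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(varS)
  p <- 2 * stats::pnorm(-abs(z))
  list(tau = tau, p = p, n = n)
}

#' Kendall correlation matrix
#'
#' Applies [kendall_tau()] to every pair of numeric variables and flags
#' significance at `alpha` (per-pair by default; optional
#' Benjamini-Hochberg correction across the upper triangle).
#'
#' @param table Data frame; non-numeric and constant columns are dropped.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `kendall_matrix`: list with `tau`, `p`,
#'   `significant` matrices and `variables`.
#' @export
kendall_matrix <- function(table, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  num <- table[vapply(table, is.numeric, logical(1))]
  keep <- vapply(num, function(x) stats::sd(x, na.rm = TRUE) > 0, logical(1))
  num <- num[keep]
  v <- names(num); k <- length(v)
  tau <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(tau) <- dimnames(p) <- list(v, v)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    kt <- kendall_tau(num[[i]], num[[j]])
    tau[i, j] <- tau[j, i] <- kt$tau
    p[i, j] <- p[j, i] <- kt$p
  }
  if (adjust == "BH") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(tau = tau, p = p, significant = !is.na(p) & p < alpha,
                 variables = v, alpha = alpha),
            class = "kendall_matrix")
}

#' @export
print.kendall_matrix <- function(x, ...) {
  cat(sprintf("<kendall_matrix> %d variables, %d significant pairs (alpha = %g)\n",
              length(x$variables), sum(x$significant[upper.tri(x$significant)]),
              x$alpha))
  invisible(x)
}

#' Intra-observer intraclass correlation, ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC (the
#' recommended form for intra-rater reliability with a fixed rater),
#' estimated from the two-way ANOVA mean squares, with the F-based 95%
#' confidence interval of McGraw & Wong.
#'
#' @param session1,session2 Paired numeric vectors (n >= 5), one value per
#'   subject per session.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `icc_result`: `estimate`, `ci` (low, high),
#'   `ms` (mean squares), `n`, `k`.
#' @export
icc_intra <- function(session1, session2, conf = 0.95) {
  stopifnot(length(session1) == length(session2))
  ok <- !is.na(session1) & !is.na(session2)
  y <- cbind(session1[ok], session2[ok])
  n <- nrow(y); k <- 2L
  if (n < 5) stop("need at least 5 subjects for a stable ICC interval")
  if (stats::var(as.vector(y)) == 0) stop("degenerate data: zero total variance")

  row_m <- rowMeans(y); col_m <- colMeans(y); g <- mean(y)
  MSR <- k * sum((row_m - g)^2) / (n - 1)          # between subjects
  MSC <- n * sum((col_m - g)^2) / (k - 1)          # between sessions
  SSE <- sum((y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  r <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))

  if (1 - r < 1e-12) {      # error-free agreement: interval collapses
    return(structure(list(estimate = r, ci = c(lower = r, upper = r),
                          ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                          n = n, k = k, conf = conf),
                     class = "icc_result"))
  }

  alpha <- 1 - conf
  a <- k * r / (n * (1 - r)); b <- 1 + k * r * (n - 1) / (n * (1 - r))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)

  structure(list(estimate = r, ci = c(lower = lower, upper = upper),
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n, k = k,
                 conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f; %.3f] (n = %d, k = %d)\n",
              x$estimate, x$ci["lower"], x$ci["upper"], x$n, x$k))
  invisible(x)
}

#' ICC table for two measurement sessions
#'
#' @param table1,table2 Data frames of identical shape (subjects x
#'   measures), session 1 and session 2.
#' @return Data frame: `variable`, `icc`, `ci_low`, `ci_high`.
#' @export
icc_table <- function(table1, table2) {
  num <- intersect(names(table1)[vapply(table1, is.numeric, logical(1))],
                   names(table2)[vapply(table2, is.numeric, logical(1))])
  rows <- lapply(num, function(v) {
    r <- tryCatch(icc_intra(table1[[v]], table2[[v]]),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(variable = v, icc = r$estimate,
               ci_low = unname(r$ci["lower"]),
               ci_high = unname(r$ci["upper"]))
  })
  do.call(rbind, rows)
}

#' Principal component analysis of standardized measures
#'
#' Variables are standardized to z-scores and the correlation matrix is
#' eigen-decomposed. Variable coordinates are loadings scaled by the
#' square root of the eigenvalue (so coordinates are correlations with the
#' components, as drawn on a correlation circle); cos^2 values quantify
#' the quality of representation of each variable on each dimension.
#'
#' @param table Data frame; non-numeric columns are ignored.
#' @return Object of class `pca_result`: `eigenvalues`, `var_pct`,
#'   `coords` (variables x dims), `cos2`, `scores` (subjects x dims).
#' @export
pca_measures <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(num) < 3 || ncol(num) < 2)
    stop("PCA needs at least 3 complete rows and 2 variables")
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant column(s): ", paste(names(num)[sds == 0], collapse = ", "))
  Z <- scale(as.matrix(num))
  C <- stats::cor(as.matrix(num))
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  coords <- e$vectors %*% diag(sqrt(ev))
  dimnames(coords) <- list(colnames(Z), paste0("Dim", seq_along(ev)))
  scores <- Z %*% e$vectors
  colnames(scores) <- paste0("Dim", seq_along(ev))
  structure(list(eigenvalues = ev, var_pct = 100 * ev / sum(ev),
                 coords = coords, cos2 = coords^2, scores = scores,
                 rotation = e$vectors),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> explained variance (%):",
      paste(sprintf("%.1f", utils::head(x$var_pct, 5)), collapse = ", "),
      "...\n")
  invisible(x)
}
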