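# Covariance network construction: per-vertex confound residualization,
# vertex-wise Pearson network, signed strength maps.

#' Residualize myelin maps against the confound design
#'
#' Fits, for every vertex independently, ordinary least squares of the
#' myelin value on the design `[1, age, age^2, gender, age x gender]` and
#' returns observed minus fitted values. Age is entered as given (not
#' centered) to follow the stated model literally; a rank check guards
#' against the resulting collinearity risk (e.g. a single-gender cohort
#' makes the interaction column collinear with age).
#'
#' @param cohort an `mcn_cohort`, or a list with `myelin` (subjects x
#'   vertices matrix) and `covariates` (data.frame with numeric `age` and
#'   `gender`).
#' @return An object of class `mcn_residuals`: `residuals` (subjects x
#'   vertices, columns mean-zero), `coefficients` (5 x vertices, rows
#'   `(Intercept)`, `age`, `age2`, `gender`, `age_x_gender`) and `design`.
#' @export
residualize <- function(cohort) {
  M <- check_matrix(cohort$myelin, "myelin")
  cov <- cohort$covariates
  if (is.null(cov) || !all(c("age", "gender") %in% names(cov))) {
    stopf("'covariates' must contain 'age' and 'gender'")
  }
  if (nrow(cov) != nrow(M)) {
    stopf("covariate rows (%d) do not match subjects (%d)", nrow(cov), nrow(M))
  }
  n <- nrow(M)
  if (n < 6L) stopf("need >= 6 subjects for the 5-column design (got %d)", n)
  age <- as.numeric(cov$age); gender <- as.numeric(cov$gender)
  X <- cbind(`(Intercept)` = 1, age = age, age2 = age^2, gender = gender,
             age_x_gender = age * gender)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, M)
  res <- qr.resid(qx, M)
  dimnames(res) <- dimnames(M)
  rownames(coef) <- colnames(X)
  out <- list(residuals = res, coefficients = coef, design = X)
  class(out) <- "mcn_residuals"
  out
}

#' @export
print.mcn_residuals <- function(x, ...) {
  cat("Residual myelin:", nrow(x$residuals), "subjects x", ncol(x$residuals),
      "vertices (design: 1, age, age^2, gender, age x gender)\n")
  invisible(x)
}

#' @noRd
as_residual_matrix <- function(residuals) {
  if (inherits(residuals, "mcn_residuals")) residuals$residuals
  else check_matrix(residuals, "residuals")
}

#' @noRd
check_column_variance <- function(R, what = "vertex") {
  v <- colSums(sweep(R, 2L, colMeans(R))^2)
  bad <- which(v <= .Machine$double.xmin)
  if (length(bad)) {
    stopf("zero-variance %s column(s): %s%s", what,
          paste(head(bad, 10L), collapse = ", "),
          if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  }
  invisible(TRUE)
}

#' Vertex-wise Pearson covariance network
#'
#' Computes the full vertex-by-vertex Pearson correlation matrix of residual
#' myelin across subjects. Zero-variance vertices are an error (not silently
#' dropped) so that the vertex set stays synchronized with annotation maps.
#'
#' @param residuals an `mcn_residuals` object or a subjects x vertices
#'   numeric matrix.
#' @return An object of class `mcn_covnet`: `rho` (symmetric, unit
#'   diagonal) and `n_subjects`.
#' @export
covariance_network <- function(residuals) {
  R <- as_residual_matrix(residuals)
  if (nrow(R) < 3L) stopf("need >= 3 subjects to correlate (got %d)", nrow(R))
  check_column_variance(R)
  rho <- stats::cor(R)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  # enforce exact symmetry against accumulated floating-point asymmetry
  rho <- (rho + t(rho)) / 2
  out <- list(rho = rho, n_subjects = nrow(R))
  class(out) <- "mcn_covnet"
  out
}

#' @export
print.mcn_covnet <- function(x, ...) {
  cat("Myelin covariance network:", ncol(x$rho), "vertices,",
      x$n_subjects, "subjects\n")
  invisible(x)
}

#' @noRd
as_rho <- function(network) {
  rho <- if (inherits(network, "mcn_covnet")) network$rho
         else check_matrix(network, "network")
  if (nrow(rho) != ncol(rho)) stopf("correlation matrix must be square")
  rho
}

#' Signed connectivity strength maps
#'
#' Per-vertex sums of off-diagonal correlations: the negative map sums
#' entries < 0, the positive map sums entries > 0, and the full map is their
#' sum, so `full = positive + negative` holds exactly at every vertex.
#' No thresholding is applied. The structural unit self-correlation on the
#' diagonal is excluded; entries exactly 0 contribute to neither signed map.
#'
#' @param network an `mcn_covnet` or a square correlation matrix.
#' @return An object of class `mcn_strength`: numeric vectors `negative`
#'   (<= 0), `positive` (>= 0) and `full`, one value per vertex.
#' @export
strength_maps <- function(network) {
  rho <- as_rho(network)
  diag(rho) <- 0
  negative <- rowSums(rho * (rho < 0))
  positive <- rowSums(rho * (rho > 0))
  out <- list(negative = negative, positive = positive,
              full = positive + negative)
  class(out) <- "mcn_strength"
  out
}

#' @export
print.mcn_strength <- function(x, ...) {
  cat("Strength maps over", length(x$full), "vertices:\n")
  cat(sprintf("  negative: mean %.4f | positive: mean %.4f | full: mean %.4f\n",
              mean(x$negative), mean(x$positive), mean(x$full)))
  invisible(x)
}

#' @export
as.data.frame.mcn_strength <- function(x, ...) {
  data.frame(vertex = seq_along(x$full), negative = x$negative,
             positive = x$positive, full = x$full)
}
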