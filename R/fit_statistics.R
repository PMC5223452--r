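#' Signed standardized residuals
#'
#' `Z = R / sqrt(Var)`. The sign of the residual is kept so diagnostic maps
#' can show the direction of misfit (an unexpectedly high response gives
#' `Z > 0`, an unexpectedly low one `Z < 0`); `Z^2 = R^2/Var` always.
#' `|Z| >= 2` marks a significant deviation from the model expectation.
#'
#' @param R residual(s) `x - p`, or a [cir_fit()] object.
#' @param Var matching model variance(s); ignored when `R` is a fit.
#' @return Standardized residual(s), same shape as `R`.
#' @export
standardized_residuals <- function(R, Var = NULL) {
  if (inherits(R, "cir_fit")) return(R$residuals$Z)
  if (is.null(Var)) stop("'Var' required when 'R' is numeric", call. = FALSE)
  if (any(Var <= 0, na.rm = TRUE)) stop("variances must be positive", call. = FALSE)
  R / sqrt(Var)
}

#' Unweighted (OUTFIT) mean-square fit statistic
#'
#' Mean of the squared standardized residuals over the observed cells of each
#' row (`margin = "person"`: \eqn{\sum_j Z_{nj}^2 / L}) or column
#' (`margin = "item"`: \eqn{\sum_n Z_{nj}^2 / N}). Under missingness the
#' denominator is the observed count. Expectation 1 under the model; values
#' above 1 flag unexpected (outlying) responses.
#'
#' @param Z standardized-residual matrix (`NA` = missing), or a [cir_fit()].
#' @param margin `"person"` (rows) or `"item"` (columns).
#' @return Numeric vector of mean squares.
#' @export
outfit_mnsq <- function(Z, margin = c("person", "item")) {
  margin <- match.arg(margin)
  if (inherits(Z, "cir_fit")) Z <- Z$residuals$Z
  sq <- Z^2
  if (margin == "person") rowMeans(sq, na.rm = TRUE) else colMeans(sq, na.rm = TRUE)
}

#' Information-weighted (INFIT) mean-square fit statistic
#'
#' \eqn{\sum R^2 / \sum Var} over the observed cells of each row or column:
#' residuals weighted by their model variance, so responses near a
#' parameter's own location dominate. Equals OUTFIT exactly whenever the
#' variance is constant across the aggregated cells.
#'
#' @param R residual matrix, or a [cir_fit()] (then `Var` is taken from it).
#' @param Var matching variance matrix.
#' @param margin `"person"` or `"item"`.
#' @return Numeric vector of mean squares.
#' @export
infit_mnsq <- function(R, Var = NULL, margin = c("person", "item")) {
  margin <- match.arg(margin)
  if (inherits(R, "cir_fit")) { Var <- R$residuals$Var; R <- R$residuals$R }
  if (is.null(Var)) stop("'Var' required when 'R' is numeric", call. = FALSE)
  obs <- !is.na(R)
  R2 <- R^2; R2[!obs] <- 0
  V <- Var; V[!obs] <- 0
  if (margin == "person") rowSums(R2) / rowSums(V) else colSums(R2) / colSums(V)
}

#' Proportion of observed variance reproduced by the model
#'
#' \deqn{R^2 = \sum_{n,j} (E_{nj} - \bar X)^2 / \sum_{n,j} (X_{nj} - \bar X)^2}
#' over non-missing cells, with \eqn{\bar X} the grand mean of the observed
#' responses (`center = "grand"`, default) or the per-item mean
#' (`center = "item"`). Equals 1 when the expectations reproduce the data and
#' 0 when they carry no more information than the mean.
#'
#' @param expected expectation grid, or a [cir_fit()] (then `observed` is
#'   taken from it).
#' @param observed observed unit-interval grid.
#' @param center `"grand"` or `"item"` centering of the mean term.
#' @return A proportion; `NA` (with a warning) when the observed variance is
#'   zero.
#' @export
model_r_squared <- function(expected, observed = NULL,
                            center = c("grand", "item")) {
  center <- match.arg(center)
  if (inherits(expected, "cir_fit")) {
    observed <- expected$data; expected <- expected$expected
  }
  obs <- !is.na(observed)
  if (sum(obs) < 2L) stop("need at least 2 observed cells", call. = FALSE)
  if (center == "grand") {
    xbar <- mean(observed[obs])
    Xc <- observed - xbar; Ec <- expected - xbar
  } else {
    cm <- colMeans(observed, na.rm = TRUE)
    Xc <- sweep(observed, 2, cm); Ec <- sweep(expected, 2, cm)
  }
  denom <- sum(Xc[obs]^2)
  if (denom == 0) {
    warning("zero observed variance; R-squared undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(Ec[obs]^2) / denom
}

#' Variance-weighted t-test between two item difficulties
#'
#' \deqn{t = (\delta_a - \delta_b) / \sqrt{1/\Sigma Var_a + 1/\Sigma Var_b}}
#' where \eqn{\Sigma Var} is the summed model variance of each item's column
#' (the reciprocal of its squared standard error). The two-sided p-value uses
#' the standard-normal tail.
#'
#' @param delta_a,delta_b the two difficulties, logits.
#' @param sumvar_a,sumvar_b the summed column variances (both positive).
#' @return An object of class `htest`.
#' @export
#' @examples
#' item_difficulty_ttest(-0.23, -0.42, 13.76, 12.39)  # t = 0.48, p = 0.63
item_difficulty_ttest <- function(delta_a, delta_b, sumvar_a, sumvar_b) {
  stopifnot(sumvar_a > 0, sumvar_b > 0)
  t <- (delta_a - delta_b) / sqrt(1 / sumvar_a + 1 / sumvar_b)
  p <- 2 * pnorm(-abs(t))
  structure(list(statistic = c(t = t), p.value = p,
                 estimate = c(difficulty.a = delta_a, difficulty.b = delta_b),
                 method = "variance-weighted t-test of two Rasch item difficulties",
                 alternative = "two.sided",
                 data.name = sprintf("delta_a = %g, delta_b = %g", delta_a, delta_b)),
            class = "htest")
}

#' F test of the model R-squared
#'
#' Simple-regression style F statistic
#' \eqn{F = R^2 (n - 2) / (1 - R^2)} with `(1, n - 2)` degrees of freedom,
#' `n` the number of observed cells.
#'
#' @param fit a [cir_fit()] object.
#' @param center passed to [model_r_squared()].
#' @return An object of class `htest` with the F statistic, df and p-value.
#' @export
model_fit_ftest <- function(fit, center = "grand") {
  r2 <- model_r_squared(fit, center = center)
  n <- sum(!is.na(fit$data))
  f <- r2 * (n - 2) / (1 - r2)
  structure(list(statistic = c(F = f), parameter = c(df1 = 1, df2 = n - 2),
                 p.value = pf(f, 1, n - 2, lower.tail = FALSE),
                 estimate = c(r.squared = r2),
                 method = "F test of Rasch model R-squared",
                 data.name = deparse(substitute(fit))),
            class = "htest")
}

# Misfit thresholds: items INFIT >= 1.5, persons OUTFIT >= 2.0, cells |Z| >= 2.
# Closed at the boundary ("less than" the threshold is acceptable fit).
.item_infit_threshold <- 1.5
.person_outfit_threshold <- 2.0
.cell_z_threshold <- 2.0

#' Fit statistics for an estimated Rasch CIR model
#'
#' Per-person and per-item INFIT and OUTFIT mean squares, the misfit flags
#' (person OUTFIT >= 2.0, item INFIT >= 1.5, cell |Z| >= 2.0), and the model
#' R-squared. With `normalize = TRUE` each mean-square set is divided by its
#' mean (see [normalize_mnsq()]): continuous responses carry far less
#' variance than the binomial working variance assumes, so raw mean squares
#' sit well below 1 and normalization restores the conventional mean of 1.0
#' for interpretation against the usual thresholds.
#'
#' @param fit a [cir_fit()] object.
#' @param normalize rescale each MNSQ set to mean 1 before flagging.
#' @param center centering for [model_r_squared()].
#' @return Object of class `cir_fitstats`: data frames `persons` (id,
#'   infit, outfit, misfit) and `items`, the logical `cell_z_flags` grid,
#'   `r_squared`, and the `normalized` flag.
#' @export
fit_statistics <- function(fit, normalize = FALSE, center = "grand") {
  stopifnot(inherits(fit, "cir_fit"))
  Z <- fit$residuals$Z
  p_out <- outfit_mnsq(Z, "person")
  i_out <- outfit_mnsq(Z, "item")
  p_in <- infit_mnsq(fit, margin = "person")
  i_in <- infit_mnsq(fit, margin = "item")
  out <- structure(list(
    persons = data.frame(person = fit$person_ids, infit = p_in, outfit = p_out,
                         misfit = FALSE, row.names = NULL),
    items = data.frame(item = fit$item_ids, infit = i_in, outfit = i_out,
                       misfit = FALSE, row.names = NULL),
    cell_z = Z, cell_z_flags = NULL,
    r_squared = model_r_squared(fit, center = center),
    normalized = FALSE), class = "cir_fitstats")
  if (normalize) normalize_mnsq(out) else reflag(out)
}

# recompute all misfit flags from the current MNSQ values and Z grid
reflag <- function(stats) {
  stats$persons$misfit <- stats$persons$outfit >= .person_outfit_threshold
  stats$items$misfit <- stats$items$infit >= .item_infit_threshold
  stats$cell_z_flags <- !is.na(stats$cell_z) & abs(stats$cell_z) >= .cell_z_threshold
  stats
}

#' Normalize mean-square fit statistics to mean 1
#'
#' Divides each value by the mean of its set so the rescaled set has mean
#' exactly 1.0. For a `cir_fitstats` object all four sets (person/item INFIT
#' and OUTFIT) are rescaled and the misfit flags recomputed on the
#' normalized values. Useful for continuous responses, whose raw mean
#' squares are far below 1 because the binomial working variance `p(1-p)`
#' overstates the true cell noise.
#'
#' @param x numeric vector of mean squares, or a `cir_fitstats` object.
#' @return Same type as `x`, rescaled.
#' @export
normalize_mnsq <- function(x) UseMethod("normalize_mnsq")

#' @export
normalize_mnsq.default <- function(x) {
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: mean of MNSQ set is not positive", call. = FALSE)
  x / m
}

#' @export
normalize_mnsq.cir_fitstats <- function(x) {
  x$persons$infit <- normalize_mnsq(x$persons$infit)
  x$persons$outfit <- normalize_mnsq(x$persons$outfit)
  x$items$infit <- normalize_mnsq(x$items$infit)
  x$items$outfit <- normalize_mnsq(x$items$outfit)
  x$normalized <- TRUE
  reflag(x)
}

#' @export
print.cir_fitstats <- function(x, ...) {
  cat(sprintf("Rasch CIR fit statistics%s\n",
              if (x$normalized) " (MNSQ normalized to mean 1)" else ""))
  cat(sprintf("  model R-squared: %.3f\n", x$r_squared))
  cat(sprintf("  person OUTFIT: mean %.3f, %d/%d flagged (>= %.1f)\n",
              mean(x$persons$outfit), sum(x$persons$misfit),
              nrow(x$persons), .person_outfit_threshold))
  cat(sprintf("  item INFIT:    mean %.3f, %d/%d flagged (>= %.1f)\n",
              mean(x$items$infit), sum(x$items$misfit),
              nrow(x$items), .item_infit_threshold))
  cat(sprintf("  cells with |Z| >= %.1f: %d\n", .cell_z_threshold,
              sum(x$cell_z_flags)))
  invisible(x)
}
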