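#' Control parameters for the joint Newton-Raphson estimation
#'
#' @param convergence_tol stop when the total absolute residual
#'   \eqn{\sum_n\sum_j |x_{nj} - p_{nj}|} over observed cells falls below this
#'   value (default 0.01). With noisy continuous data the residual total need
#'   not reach any fixed level, so a parameter-change criterion is applied as
#'   well.
#' @param change_tol stop when no parameter moved by more than this many
#'   logits in a full iteration (default 1e-4).
#' @param max_iter maximum number of outer iterations (default 1000).
#' @param variance_floor lower bound on the cell variance \eqn{p(1-p)} used in
#'   denominators, preventing division by zero as \eqn{p \to 0, 1}
#'   (default 1e-6).
#' @param max_step damping: a Newton update is truncated to at most this many
#'   logits (default 1.0).
#' @param theta_clamp estimates are confined to `[-theta_clamp, theta_clamp]`
#'   logits (default 10); extreme response strings, whose maximum-likelihood
#'   estimates diverge, are pinned at the clamp and flagged.
#' @param verbose if `TRUE`, print the per-iteration total absolute residual
#'   to stderr.
#' @return A list of class `cir_control`.
#' @export
cir_control <- function(convergence_tol = 0.01, change_tol = 1e-4,
                        max_iter = 1000L, variance_floor = 1e-6,
                        max_step = 1.0, theta_clamp = 10.0, verbose = FALSE) {
  stopifnot(convergence_tol > 0, change_tol > 0, max_iter >= 1,
            variance_floor > 0, max_step > 0, theta_clamp > 0)
  structure(list(convergence_tol = convergence_tol, change_tol = change_tol,
                 max_iter = as.integer(max_iter),
                 variance_floor = variance_floor, max_step = max_step,
                 theta_clamp = theta_clamp, verbose = isTRUE(verbose)),
            class = "cir_control")
}

#' Rescale raw responses to the unit interval
#'
#' Applies the affine transform
#' `(observed - item_min) / (item_max - item_min)` per item, leaving missing
#' cells missing. Data already on `[0, 1]` with bounds `(0, 1)` pass through
#' unchanged.
#'
#' @param x a [response_matrix()].
#' @return An object of class `rescaled_matrix`: list with `values` (all
#'   non-missing cells in `[0, 1]`), `person_ids`, `item_ids`.
#' @export
#' @examples
#' m <- response_matrix(matrix(1:5, 5, 2), item_min = 1, item_max = 5)
#' rescale(m)$values[, 1]  # 0, 0.25, 0.5, 0.75, 1
rescale <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  vals <- x$values
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    out <- which(!is.na(v) & (v < x$item_min[j] | v > x$item_max[j]))
    if (length(out))
      stop(sprintf("value outside bounds at person %s, item %s",
                   x$person_ids[out[1]], x$item_ids[j]), call. = FALSE)
    vals[, j] <- (v - x$item_min[j]) / (x$item_max[j] - x$item_min[j])
  }
  structure(list(values = vals, person_ids = x$person_ids, item_ids = x$item_ids),
            class = "rescaled_matrix")
}

#' Rasch model probability / expected fractional response
#'
#' \deqn{p = \exp(\theta - \delta) / (1 + \exp(\theta - \delta))}
#' evaluated through [stats::plogis()], numerically stable for any finite
#' logit difference. At `theta = delta` the value is exactly 0.5.
#'
#' @param theta person measure(s), logits.
#' @param delta item difficulty(ies), logits; recycled against `theta`.
#' @return Probabilities in `(0, 1)`.
#' @export
#' @examples
#' rasch_probability(0, 0)      # 0.5
#' rasch_probability(log(3), 0) # 0.75
rasch_probability <- function(theta, delta) {
  if (!is.numeric(theta) || !is.numeric(delta) ||
      any(!is.finite(theta)) || any(!is.finite(delta)))
    stop("theta and delta must be finite numerics", call. = FALSE)
  plogis(theta - delta)
}

#' Cell residual and model variance
#'
#' For a unit-interval response `x` and model expectation `p`: residual
#' `R = x - p` and working (binomial-type) variance `Var = p(1-p)`, floored
#' at `variance_floor`.
#'
#' @param x observed unit-interval response(s).
#' @param p model probability(ies) in `(0, 1)`.
#' @param variance_floor lower bound applied to `Var`.
#' @return list with components `residual` and `variance`.
#' @export
residual_and_variance <- function(x, p, variance_floor = 1e-6) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("responses must lie in [0, 1]", call. = FALSE)
  if (any(p <= 0 | p >= 1, na.rm = TRUE))
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  list(residual = x - p, variance = pmax(p * (1 - p), variance_floor))
}

#' Center item difficulties at zero
#'
#' Subtracts the mean difficulty over non-extreme items so that
#' \eqn{\sum_j \delta_j = 0}, the identification constraint of the joint
#' estimation. Extreme (flagged) items keep their clamped value.
#'
#' @param delta item difficulties, logits.
#' @param extreme logical flags; flagged items are excluded from the mean and
#'   left untouched.
#' @return Centered difficulties.
#' @export
center_items <- function(delta, extreme = rep(FALSE, length(delta))) {
  free <- !extreme
  if (!any(free)) stop("no non-extreme item to center", call. = FALSE)
  delta[free] <- delta[free] - mean(delta[free])
  delta
}

# One Newton half-step for persons: theta + sum(R)/sum(Var) over observed
# cells of the row, damped to max_step and clamped; extreme rows untouched.
step_persons <- function(theta, X, P, obs, extreme, control) {
  Var <- pmax(P * (1 - P), control$variance_floor)
  R <- (X - P)
  R[!obs] <- 0; Var[!obs] <- 0
  num <- rowSums(R); den <- rowSums(Var)
  step <- num / den
  step <- sign(step) * pmin(abs(step), control$max_step)
  new <- pmin(pmax(theta + step, -control$theta_clamp), control$theta_clamp)
  ifelse(extreme, theta, new)
}

# One Newton half-step for items: delta - sum(R)/sum(Var) over observed cells
# of the column (centering is applied by the caller).
step_items <- function(delta, X, P, obs, extreme, control) {
  Var <- pmax(P * (1 - P), control$variance_floor)
  R <- (X - P)
  R[!obs] <- 0; Var[!obs] <- 0
  num <- colSums(R); den <- colSums(Var)
  step <- -num / den
  step <- sign(step) * pmin(abs(step), control$max_step)
  new <- pmin(pmax(delta + step, -control$theta_clamp), control$theta_clamp)
  ifelse(extreme, delta, new)
}

#' Joint Rasch estimation for continuous item responses
#'
#' Rescales the data to `[0, 1]` and estimates person measures and item
#' difficulties by alternating damped Newton-Raphson updates on the
#' fractional-success score equations. All parameters start at 0 logits
#' (every person equally able, every item equally difficult); each iteration
#' performs a person half-step, refreshes the expectations, then an item
#' half-step followed by re-centering of the difficulties at zero. Iteration
#' stops when the total absolute residual \eqn{\sum|x - p|} falls below
#' `convergence_tol`, when no parameter moved by more than `change_tol`
#' logits, or at `max_iter` (with a warning, never an error).
#'
#' Persons or items whose observed responses all sit on the same scale bound
#' have divergent maximum-likelihood estimates; they are pinned at
#' `theta_clamp` (with matching sign), flagged, excluded from updates and
#' from the difficulty centering.
#'
#' @param data a [response_matrix()] or an already-rescaled `rescaled_matrix`.
#' @param control a [cir_control()] list.
#' @return Object of class `cir_fit`: person measures `theta`, difficulties
#'   `delta`, standard errors `theta_se = 1/sqrt(sum_j Var_nj)` and
#'   `delta_se = 1/sqrt(sum_n Var_nj)`, expectation grid `expected`,
#'   residual set `residuals` (`R`, `Var`, signed `Z`), the rescaled `data`,
#'   iteration count, convergence status and the per-iteration
#'   `sum_abs_residual_trace`, plus extreme-person/item flags.
#' @seealso [fit_statistics()], [write_fit_csv()]
#' @export
#' @examples
#' sim <- simulate_cir(n_persons = 50, n_items = 4, noise = "beta", seed = 7)
#' fit <- cir_fit(sim$data)
#' fit
cir_fit <- function(data, control = cir_control()) {
  stopifnot(inherits(control, "cir_control"))
  if (inherits(data, "response_matrix")) data <- rescale(data)
  if (!inherits(data, "rescaled_matrix"))
    stop("'data' must be a response_matrix or rescaled_matrix", call. = FALSE)
  X <- data$values
  N <- nrow(X); L <- ncol(X)
  if (N < 2L || L < 2L) stop("need at least 2 persons and 2 items", call. = FALSE)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0))
    stop("person with no observed responses: ",
         data$person_ids[which(rowSums(obs) == 0)[1]], call. = FALSE)
  if (any(colSums(obs) == 0))
    stop("item with no observed responses: ",
         data$item_ids[which(colSums(obs) == 0)[1]], call. = FALSE)
  Xw <- X; Xw[!obs] <- 0  # zero-filled copy; sums always masked by obs

  row_sum <- rowSums(Xw); row_n <- rowSums(obs)
  col_sum <- colSums(Xw); col_n <- colSums(obs)
  ext_p <- row_sum == 0 | row_sum == row_n   # all at the lower / upper bound
  ext_i <- col_sum == 0 | col_sum == col_n

  theta <- numeric(N); delta <- numeric(L)
  theta[ext_p] <- ifelse(row_sum[ext_p] == 0, -control$theta_clamp, control$theta_clamp)
  delta[ext_i] <- ifelse(col_sum[ext_i] == 0, control$theta_clamp, -control$theta_clamp)

  trace <- numeric(0)
  converged <- FALSE
  convergence <- "max_iter"
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    theta_old <- theta; delta_old <- delta
    P <- plogis(outer(theta, delta, "-"))
    theta <- step_persons(theta, Xw, P, obs, ext_p, control)
    P <- plogis(outer(theta, delta, "-"))
    delta <- step_items(delta, Xw, P, obs, ext_i, control)
    delta <- center_items(delta, ext_i)
    P <- plogis(outer(theta, delta, "-"))
    total_abs <- sum(abs(Xw - P)[obs])
    trace <- c(trace, total_abs)
    if (control$verbose)
      message(sprintf("iter %d: sum|O-E| = %.6f", iter, total_abs))
    max_change <- max(abs(c(theta - theta_old, delta - delta_old)))
    if (total_abs < control$convergence_tol) {
      converged <- TRUE; convergence <- "residual"; break
    }
    if (max_change < control$change_tol) {
      converged <- TRUE; convergence <- "change"; break
    }
  }
  if (!converged)
    warning("estimation did not converge in ", control$max_iter, " iterations",
            call. = FALSE)

  theta <- unname(theta); delta <- unname(delta)
  ext_p <- unname(ext_p); ext_i <- unname(ext_i)
  P <- plogis(outer(theta, delta, "-"))
  Var <- pmax(P * (1 - P), control$variance_floor)
  R <- X - P                       # NA at missing cells
  Z <- R / sqrt(Var)
  Varm <- Var; Varm[!obs] <- 0
  theta_se <- unname(1 / sqrt(rowSums(Varm)))
  delta_se <- unname(1 / sqrt(colSums(Varm)))
  dimnames(P) <- dimnames(R) <- dimnames(Z) <- dimnames(Var) <-
    list(data$person_ids, data$item_ids)

  structure(list(theta = theta, delta = delta,
                 theta_se = theta_se, delta_se = delta_se,
                 person_ids = data$person_ids, item_ids = data$item_ids,
                 data = X, expected = P,
                 residuals = list(R = R, Var = Var, Z = Z),
                 n_iter = iter, converged = converged, convergence = convergence,
                 sum_abs_residual_trace = trace,
                 extreme_persons = ext_p, extreme_items = ext_i,
                 control = control),
            class = "cir_fit")
}

#' @export
print.cir_fit <- function(x, ...) {
  cat(sprintf("Rasch CIR fit: %d persons x %d items\n",
              length(x$theta), length(x$delta)))
  cat(sprintf("  %s after %d iterations (%s criterion); sum|O-E| = %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$convergence,
              if (length(x$sum_abs_residual_trace))
                tail(x$sum_abs_residual_trace, 1) else NA_real_))
  cat(sprintf("  person measures: mean %.3f, sd %.3f logits (%d extreme)\n",
              mean(x$theta), sd(x$theta), sum(x$extreme_persons)))
  cat(sprintf("  item difficulties: %s logits (%d extreme)\n",
              paste(sprintf("%.2f", x$delta), collapse = ", "),
              sum(x$extreme_items)))
  invisible(x)
}

#' @export
coef.cir_fit <- function(object, ...) {
  list(theta = setNames(object$theta, object$person_ids),
       delta = setNames(object$delta, object$item_ids))
}

#' @export
summary.cir_fit <- function(object, ...) {
  stats <- fit_statistics(object)
  out <- list(fit = object, stats = stats)
  class(out) <- "summary.cir_fit"
  out
}

#' @export
print.summary.cir_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  model R-squared: %.3f\n", x$stats$r_squared))
  cat("Items:\n")
  print(data.frame(item = x$fit$item_ids,
                   difficulty = round(x$fit$delta, 3),
                   se = round(x$fit$delta_se, 3),
                   infit = round(x$stats$items$infit, 3),
                   outfit = round(x$stats$items$outfit, 3),
                   misfit = x$stats$items$misfit), row.names = FALSE)
  invisible(x)
}
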