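#' Simulate a response matrix under the Rasch CIR model
#'
#' Person abilities are drawn from a normal distribution on the logit scale,
#' item difficulties are either supplied (then mean-centered) or equally
#' spaced on `[-1, 1]`, and each cell expectation is the Rasch probability
#' `p = plogis(theta - delta)`. Cells are then emitted as:
#' \describe{
#'   \item{`exact`}{`x = p` — noiseless, for identifiability checks.}
#'   \item{`beta`}{`x ~ Beta(p * nu, (1 - p) * nu)` with concentration
#'     `nu = beta_precision`, so the cell mean is exactly `p` and the cell
#'     variance `p(1-p)/(nu+1)`; all draws fall strictly inside `(0, 1)`.}
#'   \item{`binary`}{`x ~ Bernoulli(p)` — classical dichotomous Rasch data.}
#' }
#'
#' @param n_persons,n_items matrix dimensions.
#' @param theta_mean,theta_sd generating ability distribution, logits.
#' @param delta explicit difficulties (mean-centered before use) or `NULL`
#'   for `n_items` equally spaced values on `[-1, 1]`.
#' @param noise `"beta"`, `"exact"` or `"binary"`.
#' @param beta_precision beta concentration `nu > 0` (default 12).
#' @param seed optional integer seed; the whole draw is reproducible from it.
#' @return list with `data` (a [response_matrix()] with bounds 0-1), and the
#'   generating `theta` and `delta`.
#' @export
#' @examples
#' sim <- simulate_cir(100, 6, noise = "beta", seed = 1)
#' range(sim$data$values)
simulate_cir <- function(n_persons, n_items, theta_mean = 0, theta_sd = 1,
                         delta = NULL, noise = c("beta", "exact", "binary"),
                         beta_precision = 12, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_persons >= 2, n_items >= 2, theta_sd >= 0)
  if (noise == "beta" && beta_precision <= 0)
    stop("beta_precision must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(delta)) delta <- seq(-1, 1, length.out = n_items)
  if (length(delta) != n_items)
    stop("length(delta) must equal n_items", call. = FALSE)
  delta <- delta - mean(delta)
  theta <- rnorm(n_persons, theta_mean, theta_sd)
  P <- plogis(outer(theta, delta, "-"))
  X <- switch(noise,
    exact = P,
    beta = matrix(rbeta(length(P), P * beta_precision, (1 - P) * beta_precision),
                  n_persons, n_items),
    binary = matrix(rbinom(length(P), 1L, P), n_persons, n_items))
  data <- response_matrix(X, item_min = 0, item_max = 1)
  list(data = data, theta = theta, delta = delta)
}

#' Simulate a full response stream for one adaptive-testing respondent
#'
#' Generates one response per bank item for a respondent of known ability so
#' an adaptive session can consume them in whatever order items are
#' selected. Reproducible from `seed`.
#'
#' @param true_theta generating ability, logits.
#' @param bank an [item_bank()].
#' @param noise `"exact"` (`x = p`) or `"beta"`.
#' @param beta_precision beta concentration when `noise = "beta"`.
#' @param seed optional integer seed.
#' @return Named numeric vector of unit-interval responses, one per bank
#'   item, in bank order.
#' @export
simulate_respondent <- function(true_theta, bank, noise = c("exact", "beta"),
                                beta_precision = 12, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(bank, "item_bank"), is.finite(true_theta))
  if (!is.null(seed)) set.seed(seed)
  p <- plogis(true_theta - bank$difficulties)
  x <- switch(noise,
    exact = p,
    beta = rbeta(length(p), p * beta_precision, (1 - p) * beta_precision))
  names(x) <- bank$item_ids
  x
}

# profile log-likelihood of one person's row (or one item's column) under
# the fractional-success model; used only by the oracle below
.oracle_row_ll <- function(theta, x, delta) {
  p <- plogis(theta - delta)
  sum(x * log(p) + (1 - x) * log(1 - p))
}

#' Brute-force estimation oracle for binary Rasch data
#'
#' An independent cross-check for [cir_fit()] that deliberately shares none
#' of its code paths: person and item parameters are estimated by
#' alternating one-dimensional derivative-free likelihood searches
#' ([stats::optimize()] on each parameter's profile log-likelihood in turn)
#' rather than Newton updates. After each sweep the difficulties are
#' re-centered at zero and the measures shifted by the same constant, which
#' leaves every `theta - delta` difference (and hence the likelihood)
#' unchanged. Sweeps repeat until no parameter moves by more than `tol`.
#'
#' @param data a [response_matrix()] whose rescaled values are all 0 or 1,
#'   with no extreme (all-0 or all-1) row or column.
#' @param tol per-sweep convergence tolerance in logits (default 1e-6).
#' @param max_sweeps safety cap on alternating sweeps.
#' @return list with `theta`, `delta` (difficulties centered at zero).
#' @export
oracle_binary_jmle <- function(data, tol = 1e-6, max_sweeps = 500L) {
  stopifnot(inherits(data, "response_matrix"))
  X <- rescale(data)$values
  if (anyNA(X)) stop("oracle requires complete data", call. = FALSE)
  if (!all(X %in% c(0, 1)))
    stop("oracle requires binary (0/1) data", call. = FALSE)
  if (any(rowSums(X) %in% c(0, ncol(X))) || any(colSums(X) %in% c(0, nrow(X))))
    stop("oracle requires no extreme (all-0 or all-1) row or column", call. = FALSE)
  N <- nrow(X); L <- ncol(X)
  theta <- numeric(N); delta <- numeric(L)
  lim <- c(-12, 12)
  for (s in seq_len(max_sweeps)) {
    theta_prev <- theta; delta_prev <- delta
    for (n in seq_len(N))
      theta[n] <- optimize(.oracle_row_ll, lim, x = X[n, ], delta = delta,
                           maximum = TRUE, tol = tol / 10)$maximum
    for (j in seq_len(L))
      delta[j] <- optimize(function(d) .oracle_row_ll(-d, X[, j], -theta),
                           lim, maximum = TRUE, tol = tol / 10)$maximum
    shift <- mean(delta)
    delta <- delta - shift
    theta <- theta - shift
    if (max(abs(c(theta - theta_prev, delta - delta_prev))) < tol) break
  }
  list(theta = theta, delta = delta)
}
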