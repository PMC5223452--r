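#' Persons-by-items response matrix with per-item scale bounds
#'
#' Container for raw observations: an `N x L` numeric grid (rows = persons or
#' units, columns = items or domains) together with the instrument's per-item
#' minimum and maximum. Missing responses are `NA` and are excluded from every
#' sum downstream. Bounds are required because estimation rescales each item
#' affinely to the unit interval ([rescale()]).
#'
#' @param values numeric matrix (or data frame) of raw responses; `NA` marks a
#'   missing cell.
#' @param item_min,item_max per-item scale bounds, each either length 1
#'   (recycled) or length `ncol(values)`. Must satisfy `item_min < item_max`.
#' @param person_ids,item_ids identifiers; default to the dimnames of `values`
#'   or to `P1..PN` / `I1..IL`.
#'
#' @return An object of class `response_matrix`: a list with elements
#'   `values`, `person_ids`, `item_ids`, `item_min`, `item_max`.
#' @seealso [read_response_csv()], [rescale()], [cir_fit()]
#' @export
#' @examples
#' m <- response_matrix(matrix(c(1, 4, 2, 5, 3, 3), 3, 2),
#'                      item_min = 1, item_max = 5)
#' m
response_matrix <- function(values, item_min, item_max,
                            person_ids = rownames(values),
                            item_ids = colnames(values)) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  N <- nrow(values); L <- ncol(values)
  if (is.null(person_ids)) person_ids <- paste0("P", seq_len(N))
  if (is.null(item_ids)) item_ids <- paste0("I", seq_len(L))
  person_ids <- as.character(person_ids); item_ids <- as.character(item_ids)
  if (length(person_ids) != N) stop("person_ids length != nrow(values)", call. = FALSE)
  if (length(item_ids) != L) stop("item_ids length != ncol(values)", call. = FALSE)
  if (anyDuplicated(person_ids))
    stop("duplicate person id: ", person_ids[duplicated(person_ids)][1], call. = FALSE)
  if (anyDuplicated(item_ids))
    stop("duplicate item id: ", item_ids[duplicated(item_ids)][1], call. = FALSE)
  item_min <- rep_len(as.numeric(item_min), L)
  item_max <- rep_len(as.numeric(item_max), L)
  if (any(!is.finite(item_min)) || any(!is.finite(item_max)))
    stop("item bounds must be finite", call. = FALSE)
  bad <- which(item_min >= item_max)
  if (length(bad))
    stop("item_min must be < item_max (item ", item_ids[bad[1]], ")", call. = FALSE)
  for (j in seq_len(L)) {
    v <- values[, j]
    out <- which(!is.na(v) & (v < item_min[j] | v > item_max[j]))
    if (length(out))
      stop(sprintf("response out of bounds at person %s, item %s: %g not in [%g, %g]",
                   person_ids[out[1]], item_ids[j], v[out[1]],
                   item_min[j], item_max[j]), call. = FALSE)
  }
  dimnames(values) <- list(person_ids, item_ids)
  structure(list(values = values, person_ids = person_ids, item_ids = item_ids,
                 item_min = item_min, item_max = item_max),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d persons x %d items (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("Item bounds:\n")
  print(data.frame(item = x$item_ids, min = x$item_min, max = x$item_max),
        row.names = FALSE)
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Missing-cell mask of a response matrix
#'
#' @param x a [response_matrix()] or `rescaled_matrix`.
#' @return logical `N x L` matrix, `TRUE` where the response is missing.
#' @export
missing_mask <- function(x) is.na(x$values)

#' Read a persons-by-items response CSV
#'
#' Expects a comma-separated UTF-8 file with a header row of item names and
#' the person/unit identifier in the first column. Empty cells are missing.
#' Parsing is locale-independent (decimal point only).
#'
#' @param path path to the CSV file.
#' @param bounds per-item scale bounds: `NULL` (default) to take the observed
#'   per-item minimum/maximum, with a warning, since the instrument's true
#'   bounds are generally wider than the observed range; a numeric
#'   `c(min, max)` applied to every item; or a two-column matrix/data frame
#'   (`min`, `max`) with one row per item.
#' @return A [response_matrix()].
#' @export
read_response_csv <- function(path, bounds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = "", strip.white = TRUE)
  if (ncol(raw) < 2L) stop("need an identifier column plus >= 1 item column", call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate person id: ", ids[duplicated(ids)][1], call. = FALSE)
  item_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(item_ids))
  for (j in seq_along(item_ids)) {
    v <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %s (person %s), column %s",
                   v[bad[1]], bad[1], ids[bad[1]], item_ids[j]), call. = FALSE)
    vals[, j] <- num
  }
  if (is.null(bounds)) {
    item_min <- suppressWarnings(apply(vals, 2, min, na.rm = TRUE))
    item_max <- suppressWarnings(apply(vals, 2, max, na.rm = TRUE))
    const <- which(!is.finite(item_min) | !is.finite(item_max) | item_min == item_max)
    if (length(const))
      stop("constant or empty item (observed min == max): ", item_ids[const[1]],
           "; supply explicit bounds", call. = FALSE)
    warning("no bounds supplied; using observed per-item minimum/maximum as scale bounds",
            call. = FALSE)
  } else if (is.numeric(bounds) && length(bounds) == 2L) {
    item_min <- bounds[1]; item_max <- bounds[2]
  } else {
    b <- as.matrix(as.data.frame(bounds))
    if (nrow(b) != length(item_ids) || ncol(b) < 2L)
      stop("'bounds' must be c(min, max) or an L x 2 table", call. = FALSE)
    item_min <- as.numeric(b[, 1]); item_max <- as.numeric(b[, 2])
  }
  response_matrix(vals, item_min, item_max, person_ids = ids, item_ids = item_ids)
}

#' Write a response matrix as CSV
#'
#' Inverse of [read_response_csv()]: header row of item names, identifier in
#' the first column, missing cells empty. Values are written at full double
#' precision so that a read/write/read round trip preserves non-missing
#' values exactly.
#'
#' @param x a [response_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  df <- as.data.frame(apply(x$values, 2, function(v)
    ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))),
    check.names = FALSE)
  if (ncol(x$values) == 1L) colnames(df) <- x$item_ids
  df <- cbind(person = x$person_ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write estimation results as CSV tables
#'
#' Writes a fit directory holding `persons.csv` (id, measure, SE, INFIT,
#' OUTFIT, flags), `items.csv` (id, difficulty, SE, INFIT, OUTFIT, flags),
#' the rescaled `responses.csv`, the standardized-residual grid
#' `zscores.csv`, and `summary.json` (R-squared, iterations, convergence).
#' Numeric columns are rounded to 6 decimals and written in a fixed column
#' order so output is deterministic.
#'
#' @param fit a [cir_fit()] result.
#' @param stats a [fit_statistics()] result for the same fit; computed if
#'   omitted.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @seealso [read_fit_dir()]
#' @export
write_fit_csv <- function(fit, stats = fit_statistics(fit), dir) {
  stopifnot(inherits(fit, "cir_fit"), inherits(stats, "cir_fitstats"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r6 <- function(x) round(x, 6)
  persons <- data.frame(person = fit$person_ids,
                        measure = r6(fit$theta), se = r6(fit$theta_se),
                        infit = r6(stats$persons$infit),
                        outfit = r6(stats$persons$outfit),
                        misfit = stats$persons$misfit,
                        extreme = fit$extreme_persons)
  items <- data.frame(item = fit$item_ids,
                      difficulty = r6(fit$delta), se = r6(fit$delta_se),
                      infit = r6(stats$items$infit),
                      outfit = r6(stats$items$outfit),
                      misfit = stats$items$misfit,
                      extreme = fit$extreme_items)
  utils::write.csv(persons, file.path(dir, "persons.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(items, file.path(dir, "items.csv"), row.names = FALSE, quote = FALSE)
  resp <- data.frame(person = fit$person_ids, r6(as.data.frame(fit$data)),
                     check.names = FALSE)
  utils::write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE, quote = FALSE)
  zs <- data.frame(person = fit$person_ids,
                   r6(as.data.frame(fit$residuals$Z)), check.names = FALSE)
  utils::write.csv(zs, file.path(dir, "zscores.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(r_squared = stats$r_squared,
                            normalized = stats$normalized,
                            n_iter = fit$n_iter, converged = fit$converged,
                            convergence = fit$convergence),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Reload a fit directory written by [write_fit_csv()]
#'
#' Reconstructs `cir_fit` and `cir_fitstats` objects (to the 6-decimal
#' precision of the CSVs) so that the diagnostic map builders and the command
#' line `wrightmap`/`kidmap` subcommands can run from files alone.
#'
#' @param dir a directory created by [write_fit_csv()].
#' @return list with elements `fit` and `stats`.
#' @export
read_fit_dir <- function(dir) {
  need <- file.path(dir, c("persons.csv", "items.csv", "responses.csv", "summary.json"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("not a fit directory, missing: ", miss[1], call. = FALSE)
  persons <- utils::read.csv(need[1], check.names = FALSE)
  items <- utils::read.csv(need[2], check.names = FALSE)
  resp <- utils::read.csv(need[3], check.names = FALSE)
  meta <- jsonlite::read_json(need[4], simplifyVector = TRUE)
  X <- as.matrix(resp[, -1, drop = FALSE])
  dimnames(X) <- list(as.character(persons$person), items$item)
  theta <- persons$measure; delta <- items$difficulty
  P <- plogis(outer(theta, delta, "-"))
  Var <- pmax(P * (1 - P), 1e-6)
  R <- X - P
  fit <- structure(list(theta = theta, delta = delta,
                        theta_se = persons$se, delta_se = items$se,
                        person_ids = as.character(persons$person),
                        item_ids = as.character(items$item),
                        data = X, expected = P,
                        residuals = list(R = R, Var = Var, Z = R / sqrt(Var)),
                        n_iter = meta$n_iter, converged = isTRUE(meta$converged),
                        convergence = meta$convergence,
                        sum_abs_residual_trace = numeric(0),
                        extreme_persons = as.logical(persons$extreme),
                        extreme_items = as.logical(items$extreme),
                        control = cir_control()),
                   class = "cir_fit")
  list(fit = fit, stats = fit_statistics(fit))
}
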