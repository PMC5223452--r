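#' Wright (person-item) map data
#'
#' Bins the non-extreme person measures into a histogram at a fixed logit bin
#' width and pairs each non-extreme item with its difficulty and INFIT mean
#' square, on one shared logit axis. Items with INFIT below 1.5 are annotated
#' as consistent with a single construct (unidimensionality).
#'
#' @param fit a [cir_fit()] object (converged).
#' @param stats matching [fit_statistics()]; computed if omitted.
#' @param bin_width person histogram bin width in logits (default 0.25).
#' @return Object of class `wright_map`: `person_bins` (data frame with
#'   `lower`, `upper`, `count`), `item_points` (data frame with `item`,
#'   `difficulty`, `infit`, `unidimensional`), `shared_axis`, `bin_width`.
#' @export
build_wright_map <- function(fit, stats = fit_statistics(fit), bin_width = 0.25) {
  stopifnot(inherits(fit, "cir_fit"), bin_width > 0)
  th <- fit$theta[!fit$extreme_persons]
  if (!length(th)) stop("no non-extreme persons to map", call. = FALSE)
  keep <- !fit$extreme_items
  lo <- floor(min(th) / bin_width) * bin_width
  hi <- ceiling(max(th) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(pmin(findInterval(th, breaks, rightmost.closed = TRUE),
                          length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  items <- data.frame(item = fit$item_ids[keep],
                      difficulty = fit$delta[keep],
                      infit = stats$items$infit[keep],
                      unidimensional = stats$items$infit[keep] < 1.5,
                      row.names = NULL)
  axis <- range(c(breaks, items$difficulty))
  structure(list(person_bins = data.frame(lower = head(breaks, -1),
                                          upper = breaks[-1], count = counts),
                 item_points = items, shared_axis = axis,
                 bin_width = bin_width,
                 n_persons = length(th)),
            class = "wright_map")
}

#' Box-plot KIDMAP data for one person
#'
#' For the focal person: per item, the cohort's five-number summary (Tukey:
#' min, lower hinge, median, upper hinge, max of all observed rescaled
#' responses), the focal response, and the focal standardized residual Z.
#' Items where the focal Z is at least +2 are listed as strengths
#' (unexpectedly high relative to counterparts), items at or below -2 as
#' weaknesses.
#'
#' @param fit a [cir_fit()] object.
#' @param person focal person identifier (must exist and be non-extreme).
#' @param stats matching [fit_statistics()]; computed if omitted.
#' @return Object of class `kidmap`: `focal_person`, `theta`, `outfit`,
#'   `misfit`, per-item data frame `per_item` (`item`, `difficulty`,
#'   `cohort_min`, `cohort_q1`, `cohort_median`, `cohort_q3`, `cohort_max`,
#'   `focal_response`, `focal_z`), and character vectors `strengths`,
#'   `weaknesses`.
#' @export
build_kidmap <- function(fit, person, stats = fit_statistics(fit)) {
  stopifnot(inherits(fit, "cir_fit"))
  n <- match(as.character(person), fit$person_ids)
  if (is.na(n)) stop("unknown person id: ", person, call. = FALSE)
  if (fit$extreme_persons[n])
    stop("person ", person, " is an extreme response string; no KIDMAP", call. = FALSE)
  L <- length(fit$item_ids)
  five <- t(vapply(seq_len(L), function(j)
    fivenum(fit$data[, j][!is.na(fit$data[, j])]), numeric(5)))
  per_item <- data.frame(item = fit$item_ids,
                         difficulty = fit$delta,
                         cohort_min = five[, 1], cohort_q1 = five[, 2],
                         cohort_median = five[, 3], cohort_q3 = five[, 4],
                         cohort_max = five[, 5],
                         focal_response = fit$data[n, ],
                         focal_z = fit$residuals$Z[n, ],
                         row.names = NULL)
  z <- per_item$focal_z
  structure(list(focal_person = fit$person_ids[n],
                 theta = fit$theta[n],
                 outfit = stats$persons$outfit[n],
                 misfit = stats$persons$misfit[n],
                 per_item = per_item,
                 strengths = per_item$item[!is.na(z) & z >= 2],
                 weaknesses = per_item$item[!is.na(z) & z <= -2]),
            class = "kidmap")
}

#' Item-characteristic-curve and OUTFIT overlay data
#'
#' The model expectation as a function of the logit difference
#' `theta - delta`, sampled over the fitted range, overlaid with one point
#' per person positioned at its measure (horizontal) and OUTFIT mean square
#' (vertical), plus the OUTFIT = 2.0 reference line above which responses
#' are aberrant.
#'
#' @param fit a [cir_fit()] object.
#' @param stats matching [fit_statistics()]; computed if omitted.
#' @param n_grid number of curve sample points.
#' @return Object of class `icc_overlay`: `curve` (data frame `logit`,
#'   `expected`, strictly increasing), `person_points` (data frame `person`,
#'   `theta`, `outfit`, `flagged`), `flag_line`.
#' @export
build_icc_overlay <- function(fit, stats = fit_statistics(fit), n_grid = 101L) {
  stopifnot(inherits(fit, "cir_fit"))
  lo <- min(fit$theta - max(fit$delta)) - 1
  hi <- max(fit$theta - min(fit$delta)) + 1
  grid <- seq(lo, hi, length.out = n_grid)
  structure(list(curve = data.frame(logit = grid, expected = plogis(grid)),
                 person_points = data.frame(person = fit$person_ids,
                                            theta = fit$theta,
                                            outfit = stats$persons$outfit,
                                            flagged = stats$persons$misfit,
                                            row.names = NULL),
                 flag_line = 2.0),
            class = "icc_overlay")
}

#' Render diagnostic map data to a file
#'
#' `json` writes the structured plot data verbatim (byte-deterministic,
#' the machine-readable surface); `svg` and `png` render the corresponding
#' plot method with a fixed style.
#'
#' @param x a `wright_map`, `kidmap` or `icc_overlay` object.
#' @param path output file path.
#' @param format `"json"`, `"svg"` or `"png"`.
#' @return `path`, invisibly.
#' @export
render_map <- function(x, path, format = c("json", "svg", "png")) {
  if (!inherits(x, c("wright_map", "kidmap", "icc_overlay")))
    stop("'x' must be a built map object", call. = FALSE)
  format <- match.arg(format)
  if (format == "json") {
    payload <- unclass(x)
    payload$.type <- class(x)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE, null = "null")
  } else if (format == "svg") {
    grDevices::svg(path, width = 8, height = 6)
    on.exit(grDevices::dev.off())
    plot(x)
  } else {
    grDevices::png(path, width = 960, height = 720)
    on.exit(grDevices::dev.off())
    plot(x)
  }
  invisible(path)
}

#' Reload map data rendered as JSON
#'
#' @param path a JSON file written by [render_map()].
#' @return The map object, with its original class restored.
#' @export
read_map_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.type
  obj$.type <- NULL
  structure(obj, class = cls)
}

#' @export
plot.wright_map <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  b <- x$person_bins
  graphics::barplot(b$count, horiz = TRUE, names.arg = sprintf("%.2f", b$lower),
                    las = 1, cex.names = 0.6, xlab = "persons",
                    ylab = "measure (logits)", main = "Person distribution",
                    col = "grey70", border = NA)
  it <- x$item_points
  graphics::plot(it$infit, it$difficulty, pch = 19,
                 xlim = range(c(0.5, 1.6, it$infit)),
                 ylim = x$shared_axis,
                 xlab = "item INFIT MNSQ", ylab = "difficulty (logits)",
                 main = "Items")
  graphics::abline(v = 1.5, lty = 2, col = "red")
  graphics::text(it$infit, it$difficulty, it$item, pos = 4, cex = 0.7)
  invisible(x)
}

#' @export
plot.kidmap <- function(x, ...) {
  pi <- x$per_item
  L <- nrow(pi)
  stats <- t(as.matrix(pi[, c("cohort_min", "cohort_q1", "cohort_median",
                              "cohort_q3", "cohort_max")]))
  bx <- list(stats = stats, n = rep(1, L), conf = NULL,
             out = numeric(0), group = numeric(0), names = pi$item)
  graphics::bxp(bx, las = 2, ylim = c(0, 1), ylab = "rescaled response",
                main = sprintf("KIDMAP: %s (theta %.2f, OUTFIT %.2f)",
                               x$focal_person, x$theta, x$outfit))
  cols <- ifelse(pi$focal_z >= 2, "blue",
                 ifelse(pi$focal_z <= -2, "red", "black"))
  graphics::points(seq_len(L), pi$focal_response, pch = 19, col = cols, cex = 1.3)
  graphics::legend("bottomleft", pch = 19, col = c("blue", "red", "black"),
                   legend = c("strength (Z >= 2)", "weakness (Z <= -2)", "typical"),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.icc_overlay <- function(x, ...) {
  graphics::plot(x$curve$logit, x$curve$expected, type = "l", lwd = 2,
                 ylim = c(0, max(1, x$person_points$outfit)),
                 xlab = "theta - delta (logits)",
                 ylab = "expected response / OUTFIT MNSQ",
                 main = "Item characteristic curve with person OUTFIT")
  pp <- x$person_points
  graphics::points(pp$theta, pp$outfit, pch = ifelse(pp$flagged, 17, 1),
                   col = ifelse(pp$flagged, "red", "grey40"))
  graphics::abline(h = x$flag_line, lty = 2, col = "red")
  invisible(x)
}
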