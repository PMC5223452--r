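#' Calibrated Rasch item bank
#'
#' Holds item identifiers and difficulties (logits) for adaptive testing.
#' The engine is Rasch-only: every item discriminates equally (slope 1), so
#' no discrimination column exists.
#'
#' @param item_ids unique identifiers.
#' @param difficulties finite difficulties in logits, one per item.
#' @return Object of class `item_bank`.
#' @export
item_bank <- function(item_ids, difficulties) {
  item_ids <- as.character(item_ids)
  difficulties <- as.numeric(difficulties)
  if (length(item_ids) != length(difficulties))
    stop("item_ids and difficulties must have equal length", call. = FALSE)
  if (anyDuplicated(item_ids))
    stop("duplicate item id in bank: ", item_ids[duplicated(item_ids)][1],
         call. = FALSE)
  if (any(!is.finite(difficulties)))
    stop("difficulties must be finite", call. = FALSE)
  structure(list(item_ids = item_ids, difficulties = difficulties),
            class = "item_bank")
}

#' Read an item bank CSV (columns `item`, `difficulty`)
#' @param path CSV file path.
#' @return An [item_bank()].
#' @export
read_item_bank_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- tolower(colnames(df))
  i <- match(c("item", "difficulty"), cols)
  if (any(is.na(i)))
    stop("bank CSV needs columns 'item' and 'difficulty'", call. = FALSE)
  item_bank(df[[i[1]]], df[[i[2]]])
}

#' Control parameters for an adaptive-testing session
#'
#' @param stop_resi stop when the residual-trail value (mean of the last
#'   three absolute changes in the provisional measure) falls strictly below
#'   this threshold (default 0.05). The rule is inactive until four
#'   provisional estimates exist.
#' @param max_items maximum items to administer; `NULL` means the bank size.
#' @param theta_clamp provisional measures confined to this many logits.
#' @param max_step Newton damping for the provisional-measure update.
#' @return A list of class `cat_control`.
#' @export
cat_control <- function(stop_resi = 0.05, max_items = NULL,
                        theta_clamp = 10.0, max_step = 1.0) {
  stopifnot(stop_resi > 0, theta_clamp > 0, max_step > 0)
  structure(list(stop_resi = stop_resi, max_items = max_items,
                 theta_clamp = theta_clamp, max_step = max_step),
            class = "cat_control")
}

#' Start an adaptive-testing session
#'
#' The provisional measure starts at 0 logits (the same origin convention as
#' the joint estimation).
#'
#' @param bank an [item_bank()].
#' @param control a [cat_control()].
#' @return Object of class `cat_state`.
#' @export
cat_start <- function(bank, control = cat_control()) {
  stopifnot(inherits(bank, "item_bank"), inherits(control, "cat_control"))
  if (is.null(control$max_items)) control$max_items <- length(bank$item_ids)
  structure(list(bank = bank, control = control,
                 administered = integer(0), responses = numeric(0),
                 theta = 0, theta_trail = numeric(0),
                 mse = NA_real_, resi = NA_real_,
                 corr = NA_real_, corr_flat = FALSE,
                 extreme = FALSE,
                 stopped = FALSE, stop_reason = NA_character_),
            class = "cat_state")
}

#' Select the next item to administer
#'
#' Maximum-information selection: among unadministered items, the one whose
#' Rasch information `p(1-p)` at the current provisional measure is largest
#' — equivalently the difficulty nearest the measure. Ties break to the
#' lowest bank index. Items are never repeated within a session.
#'
#' @param state a `cat_state`.
#' @param bank the session's bank (defaults to `state$bank`).
#' @return The selected item's bank index (named with its id).
#' @export
select_next_item <- function(state, bank = state$bank) {
  stopifnot(inherits(state, "cat_state"))
  avail <- setdiff(seq_along(bank$item_ids), state$administered)
  if (!length(avail)) stop("item bank exhausted", call. = FALSE)
  d <- abs(state$theta - bank$difficulties[avail])
  idx <- avail[which.min(d)]   # which.min takes the first = lowest index on ties
  names(idx) <- bank$item_ids[idx]
  idx
}

# Provisional measure: root of the score equation sum(x_i - p_i) = 0 over
# administered items, by damped Newton from the previous value. All-bound
# response strings have no finite root and are pinned at the clamp.
cat_update_theta <- function(theta, x, delta, control) {
  n <- length(x)
  if (sum(x) <= 0) return(list(theta = -control$theta_clamp, extreme = TRUE))
  if (sum(x) >= n) return(list(theta = control$theta_clamp, extreme = TRUE))
  for (k in seq_len(200L)) {
    p <- plogis(theta - delta)
    f <- sum(x - p)
    fp <- max(sum(p * (1 - p)), 1e-10)
    step <- f / fp
    step <- sign(step) * min(abs(step), control$max_step)
    theta <- min(max(theta + step, -control$theta_clamp), control$theta_clamp)
    if (abs(step) < 1e-10) break
  }
  list(theta = theta, extreme = FALSE)
}

#' Standard error of the provisional measure
#'
#' `MSE = 1 / sqrt(sum_i p_i (1 - p_i))` over the administered items,
#' evaluated at the current provisional measure. Strictly decreases as items
#' are added.
#'
#' @param state a `cat_state` with at least one response.
#' @param bank the session's bank (defaults to `state$bank`).
#' @return The standard-error value.
#' @export
cat_standard_error <- function(state, bank = state$bank) {
  if (!length(state$administered)) stop("no items administered", call. = FALSE)
  p <- plogis(state$theta - bank$difficulties[state$administered])
  1 / sqrt(sum(p * (1 - p)))
}

#' Residual-trail convergence value
#'
#' Mean of the absolute changes between the last three pairs of successive
#' provisional measures. Defined only once four provisional estimates exist;
#' until then `NA` and the stopping rule stays inactive.
#'
#' @param state a `cat_state`.
#' @return The residual value, or `NA` when fewer than four estimates exist.
#' @export
cat_residual <- function(state) {
  tr <- state$theta_trail
  if (length(tr) < 4L) return(NA_real_)
  mean(abs(diff(tail(tr, 4L))))
}

#' Trend correlation of the last three provisional measures
#'
#' Pearson correlation between the last three provisional measures and their
#' step numbers; advisory only (displayed, never a stop criterion). The
#' flatter the trend, the more stable the measure. A flat (zero-variance)
#' triple has undefined correlation and is reported as 0 with the flatness
#' flag set.
#'
#' @param state a `cat_state`.
#' @return list with `corr` and logical `flat`; `corr` is `NA` with fewer
#'   than three estimates.
#' @export
cat_trend_corr <- function(state) {
  tr <- state$theta_trail
  if (length(tr) < 3L) return(list(corr = NA_real_, flat = FALSE))
  y <- tail(tr, 3L)
  if (sd(y) == 0) return(list(corr = 0, flat = TRUE))
  list(corr = cor(seq_along(y), y), flat = FALSE)
}

#' Administer one adaptive-testing step
#'
#' Records the response to `item` (auto-selected by [select_next_item()]
#' when omitted), re-estimates the provisional measure, and updates the
#' standard error, residual trail and trend correlation. The session stops
#' with reason `"residual"` when the residual value falls strictly below
#' `stop_resi` (only once the rule is defined, i.e. after four estimates),
#' `"bank_exhausted"` when no item remains, or `"max_items"` at the item
#' cap.
#'
#' @param state a running `cat_state`.
#' @param response the observed response on the unit interval.
#' @param item optional bank index to administer instead of the
#'   maximum-information choice.
#' @return The updated `cat_state`.
#' @export
cat_step <- function(state, response, item = NULL) {
  stopifnot(inherits(state, "cat_state"))
  if (state$stopped) stop("session already stopped (", state$stop_reason, ")",
                          call. = FALSE)
  if (!is.numeric(response) || length(response) != 1L || is.na(response) ||
      response < 0 || response > 1)
    stop("response must be a single value in [0, 1]", call. = FALSE)
  idx <- if (is.null(item)) select_next_item(state) else as.integer(item)
  if (idx %in% state$administered)
    stop("item already administered: ", state$bank$item_ids[idx], call. = FALSE)
  state$administered <- c(state$administered, idx)
  state$responses <- c(state$responses, response)
  upd <- cat_update_theta(state$theta, state$responses,
                          state$bank$difficulties[state$administered],
                          state$control)
  state$theta <- upd$theta
  state$extreme <- upd$extreme
  state$theta_trail <- c(state$theta_trail, state$theta)
  state$mse <- cat_standard_error(state)
  state$resi <- cat_residual(state)
  tc <- cat_trend_corr(state)
  state$corr <- tc$corr; state$corr_flat <- tc$flat
  n <- length(state$responses)
  if (!is.na(state$resi) && state$resi < state$control$stop_resi) {
    state$stopped <- TRUE; state$stop_reason <- "residual"
  } else if (n >= length(state$bank$item_ids)) {
    state$stopped <- TRUE; state$stop_reason <- "bank_exhausted"
  } else if (n >= state$control$max_items) {
    state$stopped <- TRUE; state$stop_reason <- "max_items"
  }
  state
}

#' @export
print.cat_state <- function(x, ...) {
  cat(sprintf("CAT session: %d/%d items administered%s\n",
              length(x$administered), length(x$bank$item_ids),
              if (x$stopped) sprintf(", stopped (%s)", x$stop_reason) else ""))
  if (length(x$administered))
    cat(sprintf("  theta %.3f, MSE %.3f, resi %s, corr %s\n",
                x$theta, x$mse,
                ifelse(is.na(x$resi), "-", sprintf("%.4f", x$resi)),
                ifelse(is.na(x$corr), "-", sprintf("%.2f", x$corr))))
  invisible(x)
}

#' @export
as.data.frame.cat_state <- function(x, ...) {
  n <- length(x$administered)
  data.frame(step = seq_len(n),
             item = x$bank$item_ids[x$administered],
             difficulty = x$bank$difficulties[x$administered],
             response = x$responses,
             theta = x$theta_trail,
             row.names = NULL)
}

#' Run a complete simulated adaptive-testing session
#'
#' Draws a full response stream for a respondent of known ability with
#' [simulate_respondent()] and administers items until the session stops.
#'
#' @param bank an [item_bank()].
#' @param true_theta the respondent's generating ability, logits.
#' @param noise `"exact"` (responses equal model expectations) or `"beta"`.
#' @param beta_precision beta concentration when `noise = "beta"`.
#' @param seed optional RNG seed for the response stream.
#' @param control a [cat_control()].
#' @return The final `cat_state`.
#' @export
cat_simulate <- function(bank, true_theta, noise = c("exact", "beta"),
                         beta_precision = 12, seed = NULL,
                         control = cat_control()) {
  noise <- match.arg(noise)
  stream <- simulate_respondent(true_theta, bank, noise = noise,
                                beta_precision = beta_precision, seed = seed)
  state <- cat_start(bank, control)
  while (!state$stopped) {
    idx <- select_next_item(state)
    state <- cat_step(state, stream[[idx]], item = idx)
  }
  state
}
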