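# Audiovisual weight indices.  For an incongruent cell with auditory
# location X and visual location Y, the index is the reported (or decoded)
# location relative to the congruent-condition locations:
#   w = (value_incongruent(A=X, V=Y) - cong_mean(X)) / (cong_mean(Y) - cong_mean(X))
# 1 = purely visual influence, 0 = purely auditory.  The congruent means
# and hence the denominators are pooled over attention x report conditions
# (and runs) across all participants to stabilise the scaling.

#' Pooled congruent-condition scaling denominators
#'
#' Means of the congruent-condition values per location, pooled across
#' participants, attention x report conditions (and runs for decoded
#' values), and the pairwise differences that scale the weight index.
#'
#' @param values A tibble with columns `aloc`, `vloc` and the value column
#'   (reported or decoded location in degrees); congruent rows are those
#'   with `aloc == vloc`.
#' @param value_col Name of the value column.
#' @param per_participant Compute means within each participant instead of
#'   pooling (sensitivity analysis; default pooled).
#' @return An object of class `avbci_denominators`: a tibble of ordered
#'   location pairs with their denominators, carrying the pooled congruent
#'   means as an attribute.
#' @export
pooled_denominators <- function(values, value_col = "response",
                                per_participant = FALSE) {
  cong <- filter(values, .data$aloc == .data$vloc)
  locs <- sort(unique(c(values$aloc, values$vloc)))
  if (!setequal(unique(cong$aloc), locs)) {
    abort("congruent cells missing for some locations.")
  }
  grp <- if (per_participant) c("participant", "aloc") else "aloc"
  means <- cong |>
    group_by(across(all_of(grp))) |>
    summarise(mean_value = mean(.data[[value_col]]), .groups = "drop") |>
    rename(location = "aloc")
  pairs <- tidyr::expand_grid(x = locs, y = locs) |> filter(.data$x < .data$y)
  mk <- function(m) {
    d <- pairs |>
      mutate(denominator = m$mean_value[match(.data$y, m$location)] -
               m$mean_value[match(.data$x, m$location)])
    if (any(d$denominator == 0)) abort("zero scaling denominator.")
    d
  }
  out <- if (per_participant) {
    means |>
      group_by(.data$participant) |>
      group_modify(~ mk(.x)) |>
      ungroup()
  } else {
    mk(means)
  }
  structure(out, class = c("avbci_denominators", class(out)),
            congruent_means = means, per_participant = per_participant)
}

denominator_means <- function(denominators) {
  attr(denominators, "congruent_means")
}

#' Audiovisual weight index table
#'
#' Computes the weight index for every incongruent observation, then
#' averages across audiovisual location combinations within each level of
#' absolute spatial disparity, yielding the participant x attention x
#' report x disparity weight table.
#'
#' @param values Tibble with `participant`, `attention`, `report`, `aloc`,
#'   `vloc` and the value column (one row per trial, or per run x
#'   condition for decoded locations).
#' @param value_col Name of the value column (`"response"` for
#'   behavioural, `"decoded"` for neural indices).
#' @param denominators Optional [pooled_denominators()] object; computed
#'   from `values` when `NULL`.
#' @return A tibble of class `avbci_weights`: `participant`, `attention`,
#'   `report`, `disparity` (degrees), `w` (not clipped to `[0, 1]`).
#' @export
weight_index <- function(values, value_col = "response",
                         denominators = NULL) {
  denominators <- denominators %||%
    pooled_denominators(values, value_col = value_col)
  if (isTRUE(attr(denominators, "per_participant"))) {
    abort("per-participant denominators are not supported here; pass pooled.")
  }
  means <- denominator_means(denominators)
  m_of <- function(loc) means$mean_value[match(loc, means$location)]

  incong <- filter(values, .data$aloc != .data$vloc)
  if (nrow(incong) == 0) abort("no incongruent observations.")
  w_tbl <- incong |>
    mutate(
      w = (.data[[value_col]] - m_of(.data$aloc)) /
        (m_of(.data$vloc) - m_of(.data$aloc)),
      disparity = abs(.data$vloc - .data$aloc)
    ) |>
    group_by(.data$participant, .data$attention, .data$report,
             .data$aloc, .data$vloc, .data$disparity) |>
    summarise(w = mean(.data$w), .groups = "drop") |>
    group_by(.data$participant, .data$attention, .data$report,
             .data$disparity) |>
    summarise(w = mean(.data$w), .groups = "drop")
  class(w_tbl) <- c("avbci_weights", class(w_tbl))
  w_tbl
}
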