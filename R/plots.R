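# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_hline facet_grid facet_wrap labs theme_minimal
#'   position_dodge scale_y_continuous geom_abline
NULL

#' @export
ggplot2::autoplot

#' Plot a weight table
#'
#' Across-participant mean weight index (+/- SEM) by attention, report and
#' disparity, mirroring the standard factorial display.
#'
#' @param object An `avbci_weights` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.avbci_weights <- function(object, ...) {
  sums <- object |>
    group_by(.data$attention, .data$report, .data$disparity) |>
    summarise(mean_w = mean(.data$w), sem = sd(.data$w) / sqrt(dplyr::n()),
              .groups = "drop") |>
    mutate(disparity = factor(paste0(.data$disparity, "°")))
  ggplot(sums, aes(x = .data$report, y = .data$mean_w,
                   colour = .data$attention, group = .data$attention)) +
    geom_hline(yintercept = c(0, 1), linetype = "dotted", colour = "grey60") +
    geom_line(position = position_dodge(0.15)) +
    geom_errorbar(aes(ymin = .data$mean_w - .data$sem,
                      ymax = .data$mean_w + .data$sem),
                  width = 0.1, position = position_dodge(0.15)) +
    geom_point(position = position_dodge(0.15)) +
    facet_wrap(~disparity) +
    labs(x = "poststimulus report", y = "audiovisual weight index",
         colour = "attention") +
    theme_minimal()
}

#' Plot a model-selection result
#'
#' Protected exceedance probability per model variant.
#'
#' @param object An `avbci_bms` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.avbci_bms <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$model, y = .data$pep)) +
    geom_col(fill = "grey30") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = "protected exceedance probability",
         subtitle = paste0("BOR = ", signif(object$bor, 3))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot decoded against true locations
#'
#' Congruent-condition decoded locations against the true stimulus
#' locations, one panel per participant when present.
#'
#' @param object An `avbci_decoded` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.avbci_decoded <- function(object, ...) {
  cong <- filter(object, .data$aloc == .data$vloc)
  p <- ggplot(cong, aes(x = .data$aloc, y = .data$decoded)) +
    geom_abline(linetype = "dotted", colour = "grey60") +
    geom_point(alpha = 0.5) +
    labs(x = "true location (deg)", y = "decoded location (deg)") +
    theme_minimal()
  if ("participant" %in% names(object)) p <- p + facet_wrap(~participant)
  p
}

#' Plot observed versus predicted response proportions for a fit
#'
#' One panel per attention x report condition; points are observed
#' proportions, lines the model-predicted probabilities at the fitted
#' parameters.
#'
#' @param object An `avbci_fit` object.
#' @param n_sim,seed Simulation settings for the predicted probabilities.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.avbci_fit <- function(object, n_sim = 10000, seed = 1, ...) {
  counts <- object$counts
  cells <- counts$cells
  z <- crn_draws(n_sim, nrow(cells), seed)
  pred <- cell_probs(object$params, cells, z, counts$locations)
  obs <- sweep(counts$counts, 2, colSums(counts$counts), `/`)
  d <- purrr::map_dfr(seq_len(nrow(cells)), function(c) {
    bind_cols(cells[rep(c, length(counts$locations)), ],
              tibble(button = counts$locations, observed = obs[, c],
                     predicted = pred[, c]))
  })
  ggplot(d, aes(x = .data$button)) +
    geom_line(aes(y = .data$predicted, colour = factor(.data$vloc))) +
    geom_point(aes(y = .data$observed, colour = factor(.data$vloc))) +
    facet_grid(aloc ~ attention + report,
               labeller = ggplot2::label_both) +
    labs(x = "response button (deg)", y = "proportion",
         colour = "visual loc") +
    theme_minimal()
}
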