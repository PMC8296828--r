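#' Double-log enrichment scatter of an HCT intersection analysis
#'
#' Plots each node at `x = log10(OR)`, `y = log10(-log10 p)` (see
#' [doublelog_coords()]), colouring nodes significant at q < 0.05;
#' unplottable nodes (zero overlap or p near 1) are omitted from the
#' panel, their count noted in the caption.
#'
#' @param object An `hct_intersection` tibble.
#' @param label_top Label the `label_top` smallest-q nodes (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hct_intersection <- function(object, label_top = 5, ...) {
  coords <- doublelog_coords(object$odds_ratio, object$p)
  d <- dplyr::bind_cols(dplyr::select(as_tibble(object), "node", "q", "sig05"),
                        dplyr::select(coords, "x", "y", "unplottable"))
  n_off <- sum(d$unplottable)
  d <- d[!d$unplottable, , drop = FALSE]
  lab <- d[order(d$q), ][seq_len(min(label_top, nrow(d))), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sig05), alpha = 0.8) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$node),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "grey55"),
                                 name = "q < 0.05") +
    ggplot2::labs(x = "log10 odds ratio", y = "log10(-log10 p)",
                  caption = if (n_off > 0)
                    sprintf("%d node(s) unplottable (zero overlap or p ~ 1)", n_off)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de DE tibble (`gene, fc, p`).
#' @param fc_up,fc_down,p_max Thresholds drawn as guides and used to
#'   colour the up (red) and down (blue) sets.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, fc_up = 1.25, fc_down = 0.75, p_max = 0.05) {
  validate_de_table(de)
  d <- dplyr::mutate(as_tibble(de),
    set = dplyr::case_when(
      .data$fc > fc_up & .data$p < p_max ~ "up",
      .data$fc < fc_down & .data$p < p_max ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fc), y = -log10(.data$p),
                                  colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = log2(c(fc_down, fc_up)), linetype = 3) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (prone / resistant)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Body-weight trajectories coloured by cohort
#'
#' @param cohort A cohort table (`animal_id, day, body_weight`).
#' @param assignment Optional `cohort_assignment` from [assign_cohorts()];
#'   computed with `k = 5` when omitted and at least 10 animals exist.
#' @return A ggplot object.
#' @export
plot_cohort_trajectories <- function(cohort, assignment = NULL) {
  if (is.null(assignment) && dplyr::n_distinct(cohort$animal_id) >= 10) {
    assignment <- assign_cohorts(cohort, k = 5)
  }
  d <- as_tibble(cohort)
  if (!is.null(assignment)) {
    d <- dplyr::left_join(d, dplyr::select(as_tibble(assignment),
                                           "animal_id", "cohort"),
                          by = "animal_id")
  } else {
    d$cohort <- "unassigned"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$body_weight,
                                  group = .data$animal_id,
                                  colour = .data$cohort)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(prone = "#b2182b",
                                            resistant = "#2166ac",
                                            intermediate = "grey70",
                                            unassigned = "grey50")) +
    ggplot2::labs(x = "day", y = "body weight (g)") +
    ggplot2::theme_minimal()
}

#' Heat-tile view of a cross-species conservation matrix
#'
#' One tile per (gene, node) pair and species, filled by consensome
#' percentile, with HCT calls outlined.
#'
#' @param object A `conservation_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_matrix <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("percentile_a", "percentile_b"),
                        names_to = "species", values_to = "percentile") |>
    dplyr::mutate(
      hct = ifelse(.data$species == "percentile_a", .data$hct_a, .data$hct_b),
      species = ifelse(.data$species == "percentile_a", "species A", "species B"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$gene,
                                  fill = .data$percentile)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$hct), linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 na.value = NA, name = "HCT") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), na.value = "grey90") +
    ggplot2::facet_wrap(~species) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
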