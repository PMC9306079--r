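#' Heatmap of the nitrogen marker census
#'
#' @param census_tbl Census tibble from [census()].
#' @return A ggplot object: genomes (rows) by marker groups (columns),
#'   filled by presence.
#' @export
plot_census <- function(census_tbl) {
  flag_cols <- names(census_tbl)[vapply(census_tbl, is.logical, logical(1))]
  long <- census_tbl |>
    dplyr::select("genome_id", dplyr::all_of(flag_cols)) |>
    tidyr::pivot_longer(-"genome_id", names_to = "marker",
                        values_to = "present") |>
    dplyr::mutate(
      genome_id = factor(.data$genome_id,
                         levels = rev(unique(census_tbl$genome_id))),
      marker = factor(.data$marker, levels = flag_cols))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$genome_id,
                                     fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "#2166ac"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Nitrogen-cycle marker census") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of amino-acid or B-vitamin prototrophy
#'
#' @param profiles Trophy profiles from [trophy_profiles()].
#' @param category `"amino_acid"` or `"b_vitamin"`.
#' @return A ggplot object.
#' @export
plot_trophy <- function(profiles, category = c("amino_acid", "b_vitamin")) {
  category <- match.arg(category)
  mat <- trophy_matrix(profiles, category)
  long <- tidyr::pivot_longer(mat, -"genome_id", names_to = "compound",
                              values_to = "present") |>
    dplyr::mutate(
      genome_id = factor(.data$genome_id,
                         levels = rev(unique(mat$genome_id))),
      compound = factor(.data$compound, levels = names(mat)[-1]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$compound, y = .data$genome_id,
                                     fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "#1b7837"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Biosynthetic potential:", category)) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot producer/consumer pressure per nitrogen intermediate
#'
#' @param object An `ng_exchange_network`.
#' @param ... Unused.
#' @return A ggplot object: per intermediate, the number of producing and
#'   consuming genomes; exchange candidates are flagged.
#' @exportS3Method ggplot2::autoplot
autoplot.ng_exchange_network <- function(object, ...) {
  tab <- object$intermediates |>
    dplyr::mutate(label = ifelse(.data$exchange_candidate,
                                 paste0(.data$intermediate, " *"),
                                 .data$intermediate)) |>
    tidyr::pivot_longer(c("n_producers", "n_consumers"),
                        names_to = "role", values_to = "n") |>
    dplyr::mutate(role = dplyr::recode(.data$role,
                                       n_producers = "producers",
                                       n_consumers = "consumers"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$n,
                                    fill = .data$role)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(producers = "#b2182b",
                                          consumers = "#2166ac")) +
    ggplot2::labs(x = "intermediate (* = exchange candidate)",
                  y = "genomes", fill = NULL,
                  title = "NOx producer/consumer pressure") +
    ggplot2::theme_minimal()
}
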