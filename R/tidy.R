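#' Tidiers and plots for curation results
#'
#' `tidy()` on a release manifest returns the per-family quality rows;
#' `glance()` returns a one-row summary of the release. `autoplot()`
#' methods give the standard review figures: a stacked per-family
#' composition bar chart for a release and a flag-count chart for a flags
#' tibble (class `mito_flags`, see [as_mito_flags()]).
#'
#' @param x A `mitodb_release` or `mito_flags` object.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @name release-tidiers
NULL

#' @rdname release-tidiers
#' @method tidy mitodb_release
#' @export
tidy.mitodb_release <- function(x, ...) {
  x$family_stats
}

#' @rdname release-tidiers
#' @method glance mitodb_release
#' @export
glance.mitodb_release <- function(x, ...) {
  tibble(
    version = x$version,
    n_sequences = x$n_sequences,
    n_species = x$n_species,
    n_blacklisted = length(x$blacklist)
  )
}

#' @rdname release-tidiers
#' @param object Object to plot.
#' @method autoplot mitodb_release
#' @export
autoplot.mitodb_release <- function(object, ...) {
  d <- object$family_stats %>%
    select("family", "error_seq", "similar_seq", "others_seq") %>%
    tidyr::pivot_longer(-"family", names_to = "class", values_to = "n") %>%
    mutate(class = factor(.data$class,
                          levels = c("error_seq", "similar_seq", "others_seq")))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$family, -.data$n,
                                                     sum),
                                  y = .data$n, fill = .data$class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(error_seq = "#d73027",
                                          similar_seq = "#4575b4",
                                          others_seq = "grey70")) +
    ggplot2::labs(x = NULL, y = "proportion of sequences", fill = NULL,
                  title = paste0("Annotation quality by family (",
                                 object$version, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mark a flags tibble for plotting
#'
#' @param flags Flags tibble from [detect_anomalies()].
#' @return The tibble with class `mito_flags` prepended.
#' @export
as_mito_flags <- function(flags) {
  class(flags) <- unique(c("mito_flags", class(flags)))
  flags
}

#' @rdname release-tidiers
#' @method autoplot mito_flags
#' @export
autoplot.mito_flags <- function(object, ...) {
  d <- as_tibble(object) %>% count(.data$anomaly_type, .data$color)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$anomaly_type, y = .data$n,
                                  fill = .data$color)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = "anomaly category", y = "flagged sequences",
                  title = "Detected taxonomy-vs-topology anomalies") +
    ggplot2::theme_minimal()
}
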