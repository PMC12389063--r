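#' Plot a variant tally as grouped bars
#'
#' @param object An `nr_tally` object.
#' @param ... Unused.
#' @return A ggplot object: counts per species and region, faceted by
#'   variant kind.
#' @method autoplot nr_tally
#' @export
autoplot.nr_tally <- function(object, ...) {
  long <- tidy(object) %>%
    dplyr::filter(.data$table == "region") %>%
    tidyr::separate("measure", into = c("kind", "region"), sep = "_") %>%
    dplyr::mutate(kind = ifelse(.data$kind == "snp", "SNP", "InDel"),
                  region = factor(.data$region, c("18S", "ITS", "26S")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$n,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "distinct loci", fill = "region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an in-silico CAPS digest as a virtual gel
#'
#' Fragment lengths per template and enzyme on a log scale, mimicking an
#' agarose gel lane layout.
#'
#' @param object An `nr_caps` tibble from [caps_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nr_caps
#' @export
autoplot.nr_caps <- function(object, ...) {
  lanes <- as_tibble(object) %>%
    dplyr::select("template", "bste2", "mst1") %>%
    tidyr::pivot_longer(c("bste2", "mst1"), names_to = "enzyme",
                        values_to = "fragments") %>%
    dplyr::mutate(enzyme = dplyr::recode(.data$enzyme, bste2 = "BstEII",
                                         mst1 = "MstI")) %>%
    tidyr::unnest("fragments")
  ggplot2::ggplot(lanes, ggplot2::aes(x = .data$template,
                                      y = .data$fragments)) +
    ggplot2::geom_tile(width = 0.6, height = 6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~enzyme) +
    ggplot2::labs(x = NULL, y = "fragment length (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot haplotype cluster composition
#'
#' @param object An `nr_clusters` object.
#' @param ... Unused.
#' @return A ggplot object: leaves per cluster, coloured by species.
#' @method autoplot nr_clusters
#' @export
autoplot.nr_clusters <- function(object, ...) {
  counts <- dplyr::count(object$partition, .data$cluster, .data$species)
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$cluster),
                                       y = .data$n,
                                       fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "haplotypes", fill = "species") +
    ggplot2::theme_minimal()
}
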