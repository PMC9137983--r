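# ggplot2 visualisations for the main result types.

#' Quadrant scatter of SiteScore versus DScore
#'
#' Reproduces the standard druggability quadrant view: one point per site,
#' dotted threshold lines at 0.8 on both axes dividing the plane into the
#' four regions.
#'
#' @param assessments a `site_assessment` tibble (or any tibble with
#'   `site_score` and `d_score`; `site_type` is used for colour when
#'   present)
#' @param threshold threshold lines (default 0.8)
#' @return a ggplot object
#' @export
plot_quadrants <- function(assessments, threshold = 0.8) {
  a <- as_tibble(assessments)
  p <- ggplot2::ggplot(a, ggplot2::aes(x = .data$site_score,
                                       y = .data$d_score)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dotted") +
    ggplot2::labs(x = "SiteScore (ligandability)",
                  y = "DScore (druggability)")
  if ("site_type" %in% names(a))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$site_type),
                                 size = 2)
  else p <- p + ggplot2::geom_point(size = 2)
  p + ggplot2::theme_minimal()
}

#' @describeIn plot_quadrants autoplot method for assessments
#' @param object a `site_assessment`
#' @param ... passed on
#' @export
autoplot.site_assessment <- function(object, ...) plot_quadrants(object, ...)

#' @export
autoplot.conservation_profile <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$score))
  if (!is.null(d$grade))
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = factor(.data$grade)),
                               width = 1) +
      ggplot2::scale_fill_viridis_d(name = "grade", option = "C")
  else p <- p + ggplot2::geom_col(width = 1)
  p + ggplot2::labs(x = "alignment column",
                    y = "conservation score (sd units)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.site_set <- function(object, ...) {
  d <- tidy.site_set(object)
  long <- tidyr::pivot_longer(
    d[, c("site_id", "exposure", "enclosure", "contact", "phobic",
          "philic", "balance", "donacc")],
    -"site_id", names_to = "descriptor", values_to = "value")
  ref <- reference_profile()
  refd <- tibble(descriptor = c("exposure", "enclosure", "contact",
                                "phobic", "philic", "balance", "donacc"),
                 value = c(ref$exposure, ref$enclosure, ref$contact,
                           ref$phobic, ref$philic, ref$balance, ref$donacc))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$descriptor,
                                     y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_point(data = refd, colour = "red", shape = 18, size = 3) +
    ggplot2::labs(y = "descriptor value",
                  caption = "red: average submicromolar-site profile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.consensus_clusters <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$rank),
                                  y = .data$total_contacts)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "consensus cluster rank",
                  y = "total nonbonded contacts") +
    ggplot2::theme_minimal()
}

#' Stacked secondary-structure split of conserved residues
#'
#' @param summary a `conservation_summary`
#' @return a ggplot object
#' @export
plot_conservation_summary <- function(summary) {
  stopifnot(inherits(summary, "conservation_summary"))
  d <- tibble(ss = factor(names(summary$ss_split),
                          levels = c("helix", "sheet", "loop")),
              fraction = as.numeric(summary$ss_split))
  ggplot2::ggplot(d, ggplot2::aes(x = "conserved (grade 8-9)",
                                  y = .data$fraction, fill = .data$ss)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of conserved residues") +
    ggplot2::theme_minimal()
}
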