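#' Density distribution histogram plot
#'
#' @param t cohort tibble with a density column.
#' @param bin_width histogram bin width, default 0.05.
#' @param density_col name of the density column.
#' @return a ggplot object.
#' @export
plot_density_histogram <- function(t, bin_width = 0.05, density_col = "density") {
  h <- density_histogram(t, bin_width, density_col)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start + bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.95, fill = "steelblue") +
    ggplot2::labs(x = "MR breast density", y = "Exams") +
    ggplot2::theme_minimal()
}

#' Density by age decade (box plot)
#'
#' @param t cohort tibble with `age` and a density column.
#' @param density_col name of the density column.
#' @return a ggplot object.
#' @export
plot_density_by_age <- function(t, density_col = "density") {
  d <- tibble::tibble(age_bin = bin_age(t$age), density = t[[density_col]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_bin, y = .data$density)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Age group (years)", y = "MR breast density") +
    ggplot2::theme_minimal()
}

#' Density by report category (box plot)
#'
#' @param t cohort tibble with `category` and a density column.
#' @param density_col name of the density column.
#' @return a ggplot object.
#' @export
plot_density_by_category <- function(t, density_col = "density") {
  d <- tibble::tibble(category = t$category, density = t[[density_col]])
  d <- d[!is.na(d$category), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$density)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_x_discrete(labels = function(x) sub(" areas of fibroglandular density", "", x)) +
    ggplot2::labs(x = "Report density category", y = "MR breast density") +
    ggplot2::theme_minimal()
}
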