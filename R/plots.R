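# ggplot2 views of the main result types

#' Histogram of pairwise ANI values with the detected gap
#'
#' @param pairwise Per-pair summary with an `ani` column.
#' @param gap Optional `ani_gap` (shaded when given).
#' @param binwidth Histogram bin width in ANI percentage points.
#' @return A ggplot.
#' @export
plot_ani_distribution <- function(pairwise, gap = NULL, binwidth = 0.25) {
  df <- dplyr::filter(pairwise, !is.na(.data$ani))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ani)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::labs(x = "ANI (%)", y = "genome pairs") +
    ggplot2::theme_minimal()
  if (!is.null(gap)) {
    p <- p + ggplot2::annotate("rect", xmin = gap$lo, xmax = gap$hi,
                               ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}

#' Gene-by-gene identity profile of one genome pair
#'
#' Identity of every reference gene against the partner along the genome,
#' coloured by gene class, with recombination calls marked — the per-pair
#' view in which recent exchange shows up as near-100% genes on a divergent
#' backbone.
#'
#' @param profile Tibble from [pair_profile()].
#' @return A ggplot.
#' @export
plot_pair_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$mid / 1000, y = .data$identity)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 0.8, na.rm = TRUE) +
    ggplot2::geom_point(data = dplyr::filter(profile, .data$called),
                        shape = 21, size = 2, colour = "red", fill = NA, na.rm = TRUE) +
    ggplot2::labs(x = "genome position (kb)", y = "RBM identity (%)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Violin plot of cumulative identical-gene fractions by divergence group
#'
#' @param profiles Row-bound [group_profiles()] output over references.
#' @return A ggplot.
#' @export
plot_group_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$group, y = .data$fraction)) +
    ggplot2::geom_violin(fill = "lightblue", colour = NA, alpha = 0.7, scale = "width") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = "divergence group", y = "cumulative fraction of identical genes") +
    ggplot2::theme_minimal()
}

#' Histogram of recombinant tract spans
#'
#' @param tracts Tract table from [recombinant_tracts()].
#' @param binwidth Bin width in kb.
#' @return A ggplot.
#' @export
plot_tract_lengths <- function(tracts, binwidth = 2) {
  ggplot2::ggplot(tracts, ggplot2::aes(x = .data$span_bp / 1000)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, fill = "grey35") +
    ggplot2::labs(x = "tract span (kb)", y = "tracts") +
    ggplot2::theme_minimal()
}

#' Observed vs expected F100 against ANI
#'
#' @param pairwise Per-pair summary.
#' @return A ggplot.
#' @export
plot_f100_vs_ani <- function(pairwise) {
  df <- dplyr::filter(pairwise, !is.na(.data$ani))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ani)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$f100_observed), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f100_expected), colour = "orange") +
    ggplot2::labs(x = "ANI (%)", y = "fraction of identical RBM genes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.recomb_pipeline <- function(object, type = c("ani", "f100", "groups"), ...) {
  type <- match.arg(type)
  switch(type,
         ani = plot_ani_distribution(object$pairwise, object$gap),
         f100 = plot_f100_vs_ani(object$pairwise),
         groups = plot_group_profiles(object$profiles))
}
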