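#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Line plot of an RMSD (or any per-frame) series
#' @param series tibble with `time_ps` and a value column
#' @param value name of the value column
#' @param colour optional grouping column (e.g. `component` for split RMSD)
#' @return a ggplot
#' @export
plot_series <- function(series, value = "rmsd", colour = NULL) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$time_ps, y = .data[[value]]))
  if (!is.null(colour))
    p <- p + ggplot2::aes(colour = .data[[colour]])
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = value)
}

#' Per-residue RMSF profile plot
#' @param rmsf_tbl tibble from [rmsf()]
#' @return a ggplot
#' @export
plot_rmsf <- function(rmsf_tbl) {
  df <- dplyr::mutate(rmsf_tbl, pos = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$rmsf,
                                   colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue (sequence order)", y = "RMSF (Å)")
}

#' Scree plot of a trajectory PCA
#' @param object a `pcn_pca`
#' @param ... unused
#' @method autoplot pcn_pca
#' @export
autoplot.pcn_pca <- function(object, ...) {
  df <- tidy(object)
  df <- df[seq_len(min(10, nrow(df))), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance fraction")
}
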