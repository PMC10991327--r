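# ggplot2 display helpers.

map_df <- function(m, value_name = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value_name]] <- as.vector(m)
  df[!is.na(df[[value_name]]), ]
}

#' Plot a wave's amplitude and phase maps
#'
#' Side-by-side grid maps of `rho` (intensity) and `theta` (phase, rad) for
#' one component.
#'
#' @param d A `wave_decomposition`.
#' @param k Component index.
#' @return A ggplot object.
#' @export
plot_wave_map <- function(d, k) {
  lm <- loading_map(d, k)
  df <- rbind(
    cbind(map_df(Mod(lm)), panel = "rho (intensity)"),
    cbind(map_df(Arg(lm)), panel = "theta (phase, rad)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Wave %d (%.1f%% of variance)", k,
                                  100 * d$variance_fraction[k]),
                  x = NULL, y = NULL, fill = NULL)
}

#' Plot an FC matrix
#'
#' @param fc An `fc_matrix`.
#' @return A ggplot object.
#' @export
plot_fc_matrix <- function(fc) {
  v <- unclass(fc)
  df <- expand.grid(i = seq_len(nrow(v)), j = seq_len(ncol(v)))
  df$r <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("FC (%s)", attr(fc, "source")),
                  x = NULL, y = NULL, fill = "r")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overview plot of a wave decomposition
#'
#' Variance fraction and circular variance of each retained component.
#'
#' @param object A `wave_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wave_decomposition
#' @export
autoplot.wave_decomposition <- function(object, ...) {
  df <- tidy(object)
  long <- rbind(
    data.frame(component = df$component, value = df$variance_fraction,
               what = "variance fraction"),
    data.frame(component = df$component, value = df$circular_variance,
               what = "circular variance")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$component),
                                     y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "component", y = NULL)
}

#' Plot an autocorrelation curve with its oscillator fit
#'
#' @param object An `acf_curve`.
#' @param fit Optional `oscillator_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acf_curve
#' @export
autoplot.acf_curve <- function(object, fit = NULL, ...) {
  df <- data.frame(lag = object$lags, value = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = "autocorrelation")
  if (!is.null(fit)) {
    df$fitted <- oscillator_acf(df$lag, fit$amplitude, fit$f_n, fit$xi)
    p <- p + ggplot2::geom_line(data = df,
                                ggplot2::aes(y = .data$fitted),
                                color = "red", linetype = 2)
  }
  p
}
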