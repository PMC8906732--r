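#' Plot the photophysical landscape of a run
#'
#' Scatter of oscillator strength against wavelength for the absorption and
#' fluorescence bands of every generated molecule, colored by a structural
#' descriptor — the standard picture for judging whether conjugation drives
#' the photophysics of the generated set.
#'
#' @param object an `ft_search` result (or its ledger tibble for
#'   `plot_photophysics()`).
#' @param color_by `"conjugate_length"` or `"n_aromatic_rings"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ft_search
#' @export
autoplot.ft_search <- function(object, color_by = c("conjugate_length",
                                                    "n_aromatic_rings"),
                               ...) {
  plot_photophysics(object$ledger, color_by = color_by)
}

#' @rdname autoplot.ft_search
#' @param ledger ledger tibble with photophysics and descriptor columns.
#' @export
plot_photophysics <- function(ledger, color_by = c("conjugate_length",
                                                   "n_aromatic_rings")) {
  color_by <- match.arg(color_by)
  ok <- ledger[!is.na(ledger$a_w_nm), , drop = FALSE]
  long <- dplyr::bind_rows(
    tibble(band = "absorption", wavelength_nm = ok$a_w_nm, os = ok$a_i,
           color = ok[[color_by]]),
    tibble(band = "fluorescence", wavelength_nm = ok$f_w_nm, os = ok$f_i,
           color = ok[[color_by]])
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$os,
                                     colour = .data$color)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~band, scales = "free_x") +
    ggplot2::scale_colour_viridis_c(name = gsub("_", " ", color_by)) +
    ggplot2::labs(x = "wavelength (nm)", y = "oscillator strength") +
    ggplot2::theme_minimal()
}

#' Plot the reward components
#'
#' The two Gaussian wavelength terms and the oscillator-strength term of
#' the configured variant, over a plotting range.
#'
#' @param params an [reward_params()].
#' @return a ggplot object.
#' @export
plot_reward_components <- function(params = reward_params()) {
  wl <- seq(100, 1500, by = 5)
  os <- 10^seq(-4, 0.5, by = 0.05)
  df <- dplyr::bind_rows(
    tibble(x = wl, value = wavelength_reward(wl, params$T_aw, params$sigma_a),
           component = "absorption wavelength"),
    tibble(x = wl, value = wavelength_reward(wl, params$T_fw, params$sigma_f),
           component = "fluorescence wavelength"),
    tibble(x = os, value = os_reward(os, params$T_ai, params$epsilon,
                                     params$os_variant),
           component = "oscillator strength")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "component reward") +
    ggplot2::theme_minimal()
}
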