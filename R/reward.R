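#' Photophysical profile
#'
#' The quadruple scored by the reward: absorption wavelength to the first
#' excited singlet state `a_w` (nm) with oscillator strength `a_i`, and
#' fluorescence wavelength from the S1 minimum `f_w` (nm) with oscillator
#' strength `f_i`. A profile whose evaluation failed carries
#' `status = "evaluation_failed"` and scores zero reward.
#'
#' @param a_w,f_w wavelengths in nm (positive when `status = "ok"`).
#' @param a_i,f_i dimensionless oscillator strengths (non-negative).
#' @param status `"ok"` or `"evaluation_failed"`.
#' @return an object of class `ft_profile`.
#' @examples
#' photophysical_profile(433, 0.192, 580, 0.128)
#' @export
photophysical_profile <- function(a_w = NA_real_, a_i = NA_real_,
                                  f_w = NA_real_, f_i = NA_real_,
                                  status = c("ok", "evaluation_failed")) {
  status <- match.arg(status)
  if (status == "ok") {
    vals <- c(a_w = a_w, a_i = a_i, f_w = f_w, f_i = f_i)
    if (anyNA(vals) || a_w <= 0 || f_w <= 0 || a_i < 0 || f_i < 0) {
      abort("ok profiles need positive wavelengths and non-negative oscillator strengths",
            class = "fluortree_input_error")
    }
  }
  structure(list(a_w = a_w, a_i = a_i, f_w = f_w, f_i = f_i, status = status),
            class = "ft_profile")
}

#' @export
print.ft_profile <- function(x, ...) {
  if (x$status != "ok") {
    cat("<ft_profile> evaluation failed\n")
  } else {
    cat(sprintf("<ft_profile> abs %.1f nm (OS %.3f) | fluor %.1f nm (OS %.3f)\n",
                x$a_w, x$a_i, x$f_w, x$f_i))
  }
  invisible(x)
}

#' Reward parameters
#'
#' Constants of the four-component fluorescence reward. The defaults are the
#' design targets used throughout the package: absorption/fluorescence
#' wavelength targets of 700 and 1200 nm (the near-infrared bioimaging
#' window), oscillator-strength thresholds of 0.01 for both transitions,
#' component weights 0.4/0.1/0.4/0.1 (wavelengths dominate), Gaussian widths
#' of 150 nm and a floor of 1e-8 inside the logarithm.
#'
#' Two readings of the oscillator-strength term are provided. The printed
#' form, `"literal_squared"`, squares the log-ratio *inside* tanh —
#' `tanh((log10(x + eps) - log10(T))^2)` — which rewards oscillator
#' strengths far below the threshold as much as far above it.
#' `"signed_monotone"` uses `max(0, tanh(log10(x + eps) - log10(T)))`,
#' which is zero at or below the threshold and increases monotonically above
#' it. The literal form is the default.
#'
#' @param T_aw,T_fw wavelength targets (nm).
#' @param T_ai,T_fi oscillator-strength thresholds (dimensionless).
#' @param W_aw,W_ai,W_fw,W_fi component weights; must be non-negative and
#'   sum to 1.
#' @param sigma_a,sigma_f Gaussian widths of the wavelength terms (nm).
#' @param epsilon floor added before taking log10.
#' @param os_variant `"literal_squared"` or `"signed_monotone"`.
#' @return an object of class `ft_reward_params`.
#' @export
reward_params <- function(T_aw = 700, T_fw = 1200, T_ai = 0.01, T_fi = 0.01,
                          W_aw = 0.4, W_ai = 0.1, W_fw = 0.4, W_fi = 0.1,
                          sigma_a = 150, sigma_f = 150, epsilon = 1e-8,
                          os_variant = c("literal_squared", "signed_monotone")) {
  os_variant <- match.arg(os_variant)
  w <- c(W_aw, W_ai, W_fw, W_fi)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort("reward weights must be non-negative and sum to 1",
          class = "fluortree_config_error")
  }
  if (sigma_a <= 0 || sigma_f <= 0 || epsilon <= 0) {
    abort("sigma_a, sigma_f and epsilon must be positive",
          class = "fluortree_config_error")
  }
  structure(
    list(T_aw = T_aw, T_fw = T_fw, T_ai = T_ai, T_fi = T_fi,
         W_aw = W_aw, W_ai = W_ai, W_fw = W_fw, W_fi = W_fi,
         sigma_a = sigma_a, sigma_f = sigma_f, epsilon = epsilon,
         os_variant = os_variant),
    class = "ft_reward_params")
}

#' Gaussian wavelength reward
#'
#' `exp(-(x - target)^2 / (2 sigma^2))`: equals 1 exactly at the target and
#' decays symmetrically with the detuning.
#'
#' @param x observed wavelength (nm); vectorized.
#' @param target target wavelength (nm).
#' @param sigma Gaussian width (nm), positive.
#' @return score in (0, 1].
#' @examples
#' wavelength_reward(550, 700, 150) # exp(-0.5)
#' @export
wavelength_reward <- function(x, target, sigma) {
  if (sigma <= 0) abort("sigma must be positive", class = "fluortree_config_error")
  exp(-(x - target)^2 / (2 * sigma^2))
}

#' Oscillator-strength reward
#'
#' See [reward_params()] for the two variants. Both are bounded in `[0, 1)`.
#'
#' @param x observed oscillator strength (non-negative); vectorized.
#' @param target threshold oscillator strength.
#' @param epsilon floor added before taking log10.
#' @param variant `"literal_squared"` or `"signed_monotone"`.
#' @return score in `[0, 1)`.
#' @export
os_reward <- function(x, target, epsilon = 1e-8,
                      variant = c("literal_squared", "signed_monotone")) {
  variant <- match.arg(variant)
  if (any(x < 0)) {
    abort("oscillator strength must be non-negative",
          class = "fluortree_input_error")
  }
  d <- log10(x + epsilon) - log10(target)
  if (variant == "literal_squared") tanh(d^2) else pmax(0, tanh(d))
}

#' Total photophysical reward
#'
#' Weighted sum of the four component rewards. Profiles with
#' `status = "evaluation_failed"` score 0, which keeps the reward bounded
#' and steers the search away from strings that cannot be evaluated.
#'
#' @param profile an [photophysical_profile()].
#' @param params an [reward_params()].
#' @return score in `[0, 1]`.
#' @examples
#' total_reward(photophysical_profile(433, 0.192, 580, 0.128), reward_params())
#' @export
total_reward <- function(profile, params = reward_params()) {
  stopifnot(inherits(profile, "ft_profile"), inherits(params, "ft_reward_params"))
  if (profile$status != "ok") return(0)
  params$W_aw * wavelength_reward(profile$a_w, params$T_aw, params$sigma_a) +
    params$W_ai * os_reward(profile$a_i, params$T_ai, params$epsilon, params$os_variant) +
    params$W_fw * wavelength_reward(profile$f_w, params$T_fw, params$sigma_f) +
    params$W_fi * os_reward(profile$f_i, params$T_fi, params$epsilon, params$os_variant)
}
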