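#' Photophysical filter criteria
#'
#' The three screening conditions applied to generated candidates:
#' (i) absorption oscillator strength above `min_abs_os`; (ii) fluorescence
#' wavelength above `min_fl_wavelength` with oscillator strength above
#' `min_fl_os`; (iii) absorption-to-fluorescence shift above `min_shift`,
#' so the two bands are distinguishable. "Above" is a strict inequality by
#' default; `strict = FALSE` switches every comparison to inclusive —
#' boundary cases are decided by this flag, never silently.
#'
#' @param min_abs_os minimum absorption oscillator strength (default 0.1).
#' @param min_fl_wavelength minimum fluorescence wavelength in nm
#'   (default 400).
#' @param min_fl_os minimum fluorescence oscillator strength (default 0.01).
#' @param min_shift minimum absorption-fluorescence wavelength difference in
#'   nm (default 100).
#' @param strict strict (`>`) versus inclusive (`>=`) comparisons.
#' @return an object of class `ft_filter_criteria`.
#' @export
filter_criteria <- function(min_abs_os = 0.1, min_fl_wavelength = 400,
                            min_fl_os = 0.01, min_shift = 100,
                            strict = TRUE) {
  vals <- c(min_abs_os, min_fl_wavelength, min_fl_os, min_shift)
  if (any(vals < 0)) {
    abort("filter thresholds must be non-negative",
          class = "fluortree_config_error")
  }
  structure(list(min_abs_os = min_abs_os,
                 min_fl_wavelength = min_fl_wavelength,
                 min_fl_os = min_fl_os, min_shift = min_shift,
                 strict = isTRUE(strict)),
            class = "ft_filter_criteria")
}

#' Apply the photophysical filter to one profile
#'
#' @param profile an [photophysical_profile()] with `status = "ok"`.
#' @param criteria an [filter_criteria()].
#' @return list with `pass` (logical) and `failed` (character vector naming
#'   each violated criterion: `"abs_os"`, `"fl_wavelength"`, `"fl_os"`,
#'   `"shift"`).
#' @examples
#' passes_filter(photophysical_profile(433, 0.192, 577, 0.128))
#' @export
passes_filter <- function(profile, criteria = filter_criteria()) {
  stopifnot(inherits(profile, "ft_profile"),
            inherits(criteria, "ft_filter_criteria"))
  if (profile$status != "ok") {
    abort("filter is not applicable to a failed evaluation",
          class = "fluortree_filter_error")
  }
  gt <- if (criteria$strict) `>` else `>=`
  checks <- c(
    abs_os = gt(profile$a_i, criteria$min_abs_os),
    fl_wavelength = gt(profile$f_w, criteria$min_fl_wavelength),
    fl_os = gt(profile$f_i, criteria$min_fl_os),
    shift = gt(profile$f_w - profile$a_w, criteria$min_shift)
  )
  list(pass = all(checks), failed = names(checks)[!checks])
}

#' Round half away from zero (commercial rounding) to `digits` decimals
#' @noRd
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pass percentage with 2-decimal half-up rounding
#'
#' @param n_pass,n_total pass and total counts.
#' @return percentage rounded to 2 decimals (0 when `n_total` is 0).
#' @examples
#' pass_rate_pct(87, 3643) # 2.39
#' @export
pass_rate_pct <- function(n_pass, n_total) {
  if (n_total == 0) return(0)
  .round_half_up(100 * n_pass / n_total, 2)
}

#' Filter a candidate ledger
#'
#' Applies [passes_filter()] to every `ok` row of a ledger, preserving
#' generation order. Failed-evaluation rows never pass and are reported in
#' the summary.
#'
#' @param records ledger tibble with columns `a_w_nm`, `a_i`, `f_w_nm`,
#'   `f_i` and `status` (see [mcts_search()]).
#' @param criteria an [filter_criteria()].
#' @return list with `passed` (tibble of passing rows), `report` (tibble:
#'   every row with `pass` and `failed_criteria` columns) and `summary`
#'   (tibble: `n_pass`, `n_total`, `pct_pass`).
#' @export
filter_candidates <- function(records, criteria = filter_criteria()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    abort("empty candidate table", class = "fluortree_input_error")
  }
  verdicts <- purrr::pmap(
    list(records$a_w_nm, records$a_i, records$f_w_nm, records$f_i,
         records$status %||% rep("ok", nrow(records))),
    function(a_w, a_i, f_w, f_i, status) {
      if (!identical(status, "ok") || anyNA(c(a_w, a_i, f_w, f_i))) {
        return(list(pass = FALSE, failed = "evaluation_failed"))
      }
      passes_filter(photophysical_profile(a_w, a_i, f_w, f_i), criteria)
    })
  report <- dplyr::mutate(
    records,
    pass = vapply(verdicts, `[[`, logical(1), "pass"),
    failed_criteria = vapply(verdicts, function(v) {
      paste(v$failed, collapse = ";")
    }, character(1)))
  passed <- dplyr::filter(report, .data$pass)
  list(
    passed = passed,
    report = report,
    summary = tibble(n_pass = nrow(passed), n_total = nrow(records),
                     pct_pass = pass_rate_pct(nrow(passed), nrow(records)))
  )
}

#' Pearson product-moment correlation
#'
#' Thin, contract-checked wrapper around [stats::cor()]: lengths must agree
#' and be at least 3, and both vectors must vary.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3",
          class = "fluortree_input_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance",
          class = "fluortree_correlation_error")
  }
  stats::cor(x, y, method = "pearson")
}

#' Structure-photophysics correlation table
#'
#' Pearson correlations of the two structural descriptors (aromatic ring
#' count and conjugation length) against the four photophysical quantities
#' (absorption/fluorescence wavelength and oscillator strength), computed
#' over the `ok` rows of a ledger. Descriptor columns are recomputed from
#' the canonical SMILES when the ledger does not carry them (e.g. after a
#' CSV round trip).
#'
#' @param records ledger tibble.
#' @return tibble with columns `descriptor`, `a_w_nm`, `a_i`, `f_w_nm`,
#'   `f_i` (two rows).
#' @export
correlation_table <- function(records) {
  stopifnot(is.data.frame(records))
  ok <- records[!is.na(records$a_w_nm) &
                  (records$status %||% "ok") == "ok", , drop = FALSE]
  if (nrow(ok) < 3L) {
    abort("need at least 3 evaluated records",
          class = "fluortree_input_error")
  }
  if (!all(c("n_aromatic_rings", "conjugate_length") %in% names(ok))) {
    mols <- lapply(ok$smiles_canonical, parse_smiles, enforce_elements = FALSE)
    ok$n_aromatic_rings <- vapply(mols, `[[`, integer(1), "n_aromatic_rings")
    ok$conjugate_length <- vapply(mols, `[[`, integer(1), "conjugate_length")
  }
  props <- c("a_w_nm", "a_i", "f_w_nm", "f_i")
  descs <- c(n_aromatic_rings = "aromatic_rings",
             conjugate_length = "conjugate_length")
  rows <- lapply(names(descs), function(d) {
    vals <- lapply(props, function(p) pearson_correlation(ok[[d]], ok[[p]]))
    tibble(descriptor = descs[[d]], !!!setNames(vals, props))
  })
  dplyr::bind_rows(rows)
}

#' Summarize a generation run
#'
#' Totals, pass fraction, the median generation order of the selected
#' subset (lower median for even counts) and binned
#' wavelength/oscillator-strength distributions for absorption and
#' fluorescence, stratified by the two structural descriptors.
#'
#' @param records full ledger tibble.
#' @param subset the filtered sublist (rows of `records`; e.g.
#'   `filter_candidates(records)$passed`).
#' @param wavelength_breaks,os_breaks bin edges for the distribution
#'   summaries.
#' @return list with `n_total`, `n_pass`, `pct_pass`,
#'   `median_generation_index` (`NA` and `median_defined = FALSE` for an
#'   empty subset) and `distributions` (long tibble of bin counts).
#' @export
summarize_run <- function(records, subset,
                          wavelength_breaks = seq(0, 2000, by = 100),
                          os_breaks = c(0, 0.01, 0.05, 0.1, 0.5, 1, Inf)) {
  stopifnot(is.data.frame(records), is.data.frame(subset))
  if (!all(subset$smiles_canonical %in% records$smiles_canonical)) {
    abort("subset must be drawn from records", class = "fluortree_input_error")
  }
  lower_median <- function(ix) {
    ix <- sort(ix)
    if (length(ix) == 0L) return(NA_integer_)
    ix[ceiling(length(ix) / 2)]
  }
  ok <- records[(records$status %||% "ok") == "ok" & !is.na(records$a_w_nm), ,
                drop = FALSE]
  if (!all(c("n_aromatic_rings", "conjugate_length") %in% names(ok))) {
    mols <- lapply(ok$smiles_canonical, parse_smiles, enforce_elements = FALSE)
    ok$n_aromatic_rings <- vapply(mols, `[[`, integer(1), "n_aromatic_rings")
    ok$conjugate_length <- vapply(mols, `[[`, integer(1), "conjugate_length")
  }
  bin_one <- function(band, wcol, ocol) {
    dplyr::count(
      tibble(
        band = band,
        wavelength_bin = cut(ok[[wcol]], wavelength_breaks,
                             include.lowest = TRUE),
        os_bin = cut(ok[[ocol]], os_breaks, include.lowest = TRUE),
        n_aromatic_rings = ok$n_aromatic_rings,
        conjugate_length = ok$conjugate_length),
      .data$band, .data$wavelength_bin, .data$os_bin,
      .data$n_aromatic_rings, .data$conjugate_length,
      name = "count")
  }
  dists <- dplyr::bind_rows(bin_one("absorption", "a_w_nm", "a_i"),
                            bin_one("fluorescence", "f_w_nm", "f_i"))
  list(
    n_total = nrow(records),
    n_pass = nrow(subset),
    pct_pass = pass_rate_pct(nrow(subset), nrow(records)),
    median_generation_index = lower_median(subset$generation_index),
    median_defined = nrow(subset) > 0L,
    distributions = dists
  )
}
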