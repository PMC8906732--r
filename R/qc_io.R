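#' TD-DFT job specification
#'
#' Describes one stage of the photophysics evaluation protocol: a
#' ground-state geometry optimization followed by a vertical TD-DFT
#' excitation calculation (`"s0_opt_td"`), or an excited-state geometry
#' optimization of the first singlet followed by TD-DFT at that minimum
#' (`"s1_opt_td"`). Defaults follow the protocol this generator targets:
#' B3LYP/3-21G* with the lowest 10 excited states at each minimum.
#'
#' @param level functional/basis label placed in the route section.
#' @param n_states number of excited states requested (>= 1).
#' @param stage `"s0_opt_td"` or `"s1_opt_td"`.
#' @param charge,multiplicity molecular charge and spin multiplicity.
#' @return an object of class `ft_qc_spec`.
#' @export
qc_job_spec <- function(level = "B3LYP/3-21G*", n_states = 10,
                        stage = c("s0_opt_td", "s1_opt_td"),
                        charge = 0, multiplicity = 1) {
  stage <- match.arg(stage)
  if (n_states < 1) {
    abort("n_states must be at least 1", class = "fluortree_config_error")
  }
  structure(list(level = level, n_states = as.integer(n_states),
                 stage = stage, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "ft_qc_spec")
}

#' Deterministic coordinates for a molecule
#'
#' One fixed embedding per canonical SMILES: the planar sketch coordinates
#' produced by the structure generator (z = 0). Sufficient for byte-stable
#' input decks; a real deployment would plug a 3D embedder into the same
#' slot before running the QC engine.
#'
#' @param mol an `ft_molecule` (or SMILES string).
#' @return tibble with columns `element`, `x`, `y`, `z` (Angstroms).
#' @export
embed_coordinates <- function(mol) {
  mol <- .as_molecule(mol)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(mol$smiles_canonical))
  ab <- ChemmineR::atomblock(sdf[[1]])
  tibble(element = sub("_[0-9]+$", "", rownames(ab)),
         x = round(unname(ab[, 1]), 6), y = round(unname(ab[, 2]), 6),
         z = 0)
}

#' Write a TD-DFT input deck
#'
#' Renders a Gaussian-style input deck: a route section naming the
#' functional/basis and the requested number of excited states, a title, a
#' charge/multiplicity line and the Cartesian block in Angstroms. The
#' `s1_opt_td` stage requests geometry optimization on the first excited
#' state (`td(root=1)`). Output is byte-identical for identical inputs.
#'
#' @param coords coordinate tibble from [embed_coordinates()] (columns
#'   `element`, `x`, `y`, `z`).
#' @param spec an [qc_job_spec()].
#' @param title title line.
#' @return a single string, the deck text.
#' @export
write_td_dft_input <- function(coords, spec = qc_job_spec(),
                               title = "fluortree TD-DFT job") {
  stopifnot(inherits(spec, "ft_qc_spec"))
  if (is.null(coords) || nrow(coords) == 0L ||
      !all(c("element", "x", "y", "z") %in% names(coords))) {
    abort("coordinates with element/x/y/z columns are required",
          class = "fluortree_input_error")
  }
  route <- if (spec$stage == "s0_opt_td") {
    sprintf("# opt %s td=(nstates=%d)", spec$level, spec$n_states)
  } else {
    sprintf("# opt=(td) %s td=(nstates=%d,root=1)", spec$level, spec$n_states)
  }
  atom_lines <- sprintf(" %-2s %14.6f %14.6f %14.6f",
                        coords$element, coords$x, coords$y, coords$z)
  paste(c(route, "", title, "",
          sprintf("%d %d", spec$charge, spec$multiplicity),
          atom_lines, "", ""),
        collapse = "\n")
}

.td_state_pattern <- "^\\s*Excited State\\s+([0-9]+):"

#' Parse a TD-DFT output log
#'
#' Extracts the excited-state announcement lines of the conventional form
#' (state index, excitation energy in eV, wavelength in nm, `f=` oscillator
#' strength). When geometry optimization repeats the TD block, only the
#' final block is returned. Wavelengths are recomputed from the parsed
#' energies via hc = 1239.84193 eV nm, so they are consistent with the
#' energies to full precision rather than the log's printed rounding.
#'
#' @param log log text: a single string, a character vector of lines, or a
#'   file path.
#' @return tibble with columns `state`, `energy_ev`, `wavelength_nm`, `os`,
#'   in file order; zero rows for a log with no TD block.
#' @export
parse_td_dft_output <- function(log) {
  lines <- if (length(log) == 1L && !grepl("\n", log) && file.exists(log)) {
    readLines(log, warn = FALSE)
  } else if (length(log) == 1L) {
    strsplit(log, "\n", fixed = TRUE)[[1]]
  } else {
    log
  }
  hit <- grep(.td_state_pattern, lines)
  if (length(hit) == 0L) {
    return(tibble(state = integer(0), energy_ev = numeric(0),
                  wavelength_nm = numeric(0), os = numeric(0)))
  }
  parse_one <- function(i) {
    ln <- lines[i]
    m <- regmatches(ln, regexec(
      "Excited State\\s+([0-9]+):\\s+\\S+\\s+([-0-9.eEdD+]+)\\s*eV\\s+([-0-9.eEdD+]+)\\s*nm\\s+f\\s*=\\s*([-0-9.eEdD+]+)",
      ln))[[1]]
    if (length(m) != 5L) {
      abort(sprintf("malformed excited-state line %d: %s", i, trimws(ln)),
            class = "fluortree_parse_error")
    }
    num <- suppressWarnings(as.numeric(gsub("[dD]", "e", m[2:5])))
    if (anyNA(num)) {
      abort(sprintf("malformed numeric field on line %d: %s", i, trimws(ln)),
            class = "fluortree_parse_error")
    }
    c(state = as.numeric(m[2]), energy = num[2], os = num[4])
  }
  parsed <- t(vapply(hit, parse_one, c(state = 0, energy = 0, os = 0)))
  # block boundaries: a state index that does not increase starts a new block
  st <- parsed[, "state"]
  block <- cumsum(c(TRUE, diff(st) <= 0))
  last <- block == max(block)
  tibble(state = as.integer(st[last]),
         energy_ev = unname(parsed[last, "energy"]),
         wavelength_nm = EV_NM / unname(parsed[last, "energy"]),
         os = unname(parsed[last, "os"]))
}

#' Render a synthetic TD-DFT log
#'
#' Writes excitation records back into the conventional log line format, for
#' round-trip testing and for constructing fixtures without running a QC
#' engine.
#'
#' @param records tibble with columns `state`, `energy_ev`, `os` (and
#'   optionally `wavelength_nm`; recomputed when absent).
#' @param n_blocks repeat the TD block this many times (mimicking the
#'   repeated TD sections of a geometry optimization); earlier blocks get
#'   slightly perturbed energies so that "last block wins" is observable.
#' @return a single string of log text.
#' @export
render_td_dft_log <- function(records, n_blocks = 1) {
  stopifnot(all(c("state", "energy_ev", "os") %in% names(records)))
  render_block <- function(shift) {
    e <- records$energy_ev + shift
    c(" Excitation energies and oscillator strengths:",
      sprintf(" Excited State %3d:      Singlet-A     %7.4f eV %8.2f nm  f=%.4f  <S**2>=0.000",
              records$state, e, EV_NM / e, records$os),
      "")
  }
  shifts <- rev(seq_len(n_blocks) - 1L) * 0.05
  paste(c(" Entering Link 1", unlist(lapply(shifts, render_block)),
          " Normal termination."),
        collapse = "\n")
}

#' Assemble a photophysical profile from two TD-DFT runs
#'
#' Absorption comes from state 1 of the ground-state-minimum run;
#' fluorescence from state 1 of the S1-minimum run. Wavelengths are derived
#' from the excitation energies via hc = 1239.84193 eV nm. A missing state 1
#' in either run yields an `evaluation_failed` profile.
#'
#' @param s0_records,s1_records excitation tables from
#'   [parse_td_dft_output()].
#' @return an `ft_profile`.
#' @examples
#' s0 <- tibble::tibble(state = 1L, energy_ev = 2.87, os = 0.192)
#' s1 <- tibble::tibble(state = 1L, energy_ev = 2.14, os = 0.128)
#' profile_from_runs(s0, s1)
#' @export
profile_from_runs <- function(s0_records, s1_records) {
  pick1 <- function(df) {
    if (is.null(df) || nrow(df) == 0L || !any(df$state == 1L)) return(NULL)
    df[which(df$state == 1L)[1], ]
  }
  s0 <- pick1(s0_records)
  s1 <- pick1(s1_records)
  if (is.null(s0) || is.null(s1)) {
    return(photophysical_profile(status = "evaluation_failed"))
  }
  photophysical_profile(
    a_w = EV_NM / s0$energy_ev, a_i = s0$os,
    f_w = EV_NM / s1$energy_ev, f_i = s1$os
  )
}
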