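#' @include tokenizer.R
NULL

# maximum explicit-valence table (sum of explicit bond orders) per element;
# formal charge shifts the allowance for the common N+/O-/O+ cases.
.max_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
                  P = 5, S = 6, Cl = 1, Br = 1, I = 1)

.allowed_elements <- c("H", "C", "N", "O")

# MOL-file charge codes: 0 none, 1..3 = +3..+1, 4 doublet radical, 5..7 = -1..-3
.mol_charge <- function(code) {
  ifelse(code == 0, 0L,
         ifelse(code <= 3, 4L - as.integer(code),
                ifelse(code == 4, 0L, 4L - as.integer(code))))
}

# cheap syntax screen run before OpenBabel: OpenBabel silently repairs some
# malformed strings (e.g. "C(" parses as "C"), while the contract here is
# rejection, never repair.
.smiles_syntax_ok <- function(tokens) {
  if (length(tokens) == 0L) return(FALSE)
  depth <- 0L
  prev <- ""
  ring_labels <- character(0)
  bond_syms <- c("-", "=", "#", ":", "/", "\\")
  for (tk in tokens) {
    if (tk == "(") {
      if (prev %in% c("", "(", bond_syms)) return(FALSE)
      depth <- depth + 1L
    } else if (tk == ")") {
      if (prev %in% c("(", bond_syms, "")) return(FALSE)
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (grepl("^[0-9]$|^%[0-9]{2}$", tk)) {
      if (prev %in% c("", "(")) return(FALSE)
      lbl <- sub("^%", "", tk)
      if (lbl %in% ring_labels) {
        ring_labels <- setdiff(ring_labels, lbl)
      } else {
        ring_labels <- c(ring_labels, lbl)
      }
    } else if (tk %in% bond_syms) {
      # a branch may open with a bond symbol: "C(=O)O"
      if (prev %in% c("", bond_syms)) return(FALSE)
    } else if (tk == ".") {
      if (prev %in% c("", "(", bond_syms)) return(FALSE)
    }
    prev <- tk
  }
  if (depth != 0L) return(FALSE)
  if (length(ring_labels) > 0L) return(FALSE)
  if (prev %in% c(bond_syms, "(", ".")) return(FALSE)
  TRUE
}

.is_atom_token <- function(tk) {
  grepl("^\\[", tk) | tk %in% c("B", "C", "N", "O", "P", "S", "F", "Cl",
                                "Br", "I", "b", "c", "n", "o", "p", "s")
}

.heavy_atom_tokens <- function(tokens) {
  at <- tokens[.is_atom_token(tokens)]
  at[!(at %in% c("[H]", "[2H]", "[3H]"))]
}

.canonicalize_ob <- function(text) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", text),
                  error = function(e) "")
  can <- sub("[ \t\n\r].*$", "", out)
  if (!nzchar(can)) NULL else can
}

# ring perception via ChemmineR (all rings + per-ring aromaticity), then a
# smallest-ring-basis (SSSR) selection by greedy GF(2) independence over the
# edge space, smallest rings first.
.ring_basis <- function(sdf, bonds) {
  n_bond <- nrow(bonds)
  if (n_bond == 0L) return(list(rings = list(), aromatic = logical(0)))
  n_atom <- nrow(ChemmineR::atomblock(sdf[[1]]))
  # union-find for the connected-component count in the cyclomatic number
  comp <- seq_len(n_atom)
  for (k in seq_len(n_bond)) {
    a <- comp[bonds$from[k]]; b <- comp[bonds$to[k]]
    while (comp[a] != a) a <- comp[a]
    while (comp[b] != b) b <- comp[b]
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(n_atom), function(i) {
    while (comp[i] != i) i <- comp[i]; i
  }, integer(1))
  n_sssr <- n_bond - n_atom + length(unique(roots))
  if (n_sssr <= 0L) return(list(rings = list(), aromatic = logical(0)))

  ri <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf[1], type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(ri) || length(ri$RINGS) == 0L) {
    return(list(rings = list(), aromatic = logical(0)))
  }
  atom_idx <- function(nm) as.integer(sub("^.*_", "", nm))
  ring_atoms <- lapply(ri$RINGS, atom_idx)
  bond_key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
  ring_edges <- lapply(ring_atoms, function(a) {
    b <- c(a[-1], a[1])
    sort(match(paste(pmin(a, b), pmax(a, b)), bond_key))
  })
  ok <- !vapply(ring_edges, anyNA, logical(1))
  ring_atoms <- ring_atoms[ok]; ring_edges <- ring_edges[ok]
  arom <- unname(ri$AROMATIC[ok])
  ord <- order(lengths(ring_edges),
               vapply(ring_edges, function(e) paste(e, collapse = ","),
                      character(1)))
  basis <- matrix(0L, nrow = 0L, ncol = n_bond)
  keep <- integer(0)
  for (i in ord) {
    v <- integer(n_bond); v[ring_edges[[i]]] <- 1L
    w <- v
    for (r in seq_len(nrow(basis))) {
      piv <- which(basis[r, ] == 1L)[1]
      if (w[piv] == 1L) w <- (w + basis[r, ]) %% 2L
    }
    if (any(w == 1L)) {
      basis <- rbind(basis, w)
      keep <- c(keep, i)
      if (length(keep) == n_sssr) break
    }
  }
  list(rings = ring_atoms[keep], aromatic = arom[keep])
}

#' Parse and validate a SMILES string
#'
#' Parses a SMILES string into a validated, canonicalized molecule. Invalid
#' strings (unbalanced branches or ring bonds, valence violations) are
#' rejected with an error — never silently repaired. Canonicalization and
#' kekulization are delegated to OpenBabel (via ChemmineOB); ring perception
#' to ChemmineR. The two structural descriptors used throughout the package
#' — the number of aromatic rings in the smallest ring basis and the
#' conjugation length — are computed at parse time.
#'
#' @param text a single SMILES string.
#' @param enforce_elements if `TRUE` (default), restrict elements to
#'   H, C, N, O — the composition of the training corpus this generator
#'   targets; other elements raise an element-constraint error.
#' @return an object of class `ft_molecule` with fields `smiles_input`,
#'   `smiles_canonical` (the deduplication key), `atoms` (tibble:
#'   `element`, `aromatic`), `bonds` (tibble: `from`, `to`, `order`, with
#'   kekulized orders 1/2/3), `n_aromatic_rings` and `conjugate_length`.
#' @examples
#' mol <- parse_smiles("c1ccccc1")
#' mol$n_aromatic_rings
#' mol$conjugate_length
#' @export
parse_smiles <- function(text, enforce_elements = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    abort("empty SMILES string", class = "fluortree_invalid_smiles")
  }
  tokens <- tryCatch(smiles_tokens(text), error = function(e) NULL)
  if (is.null(tokens) || !.smiles_syntax_ok(tokens)) {
    abort(sprintf("invalid SMILES (syntax): %s", text),
          class = "fluortree_invalid_smiles")
  }
  can <- .canonicalize_ob(text)
  if (is.null(can)) {
    abort(sprintf("invalid SMILES (rejected by parser): %s", text),
          class = "fluortree_invalid_smiles")
  }
  # single heavy atom: no bonds, no rings; built directly (the SDF machinery
  # needs at least one bond)
  can_tokens <- smiles_tokens(can)
  if (length(.heavy_atom_tokens(can_tokens)) == 1L &&
      length(.heavy_atom_tokens(tokens)) == 1L) {
    tk <- .heavy_atom_tokens(can_tokens)[1]
    el <- regmatches(tk, regexec("([A-IK-PR-Z][a-z]?|[bcnops])", tk))[[1]][2]
    el <- paste0(toupper(substr(el, 1, 1)), substring(el, 2))
    if (enforce_elements && !(el %in% .allowed_elements)) {
      abort(sprintf("element(s) outside {H,C,N,O}: %s (in %s)", el, text),
            class = "fluortree_element_error")
    }
    mol <- structure(
      list(smiles_input = text, smiles_canonical = can,
           atoms = tibble(element = el, aromatic = FALSE),
           bonds = tibble(from = integer(0), to = integer(0),
                          order = integer(0)),
           ring_basis = list(rings = list(), aromatic = logical(0)),
           n_aromatic_rings = 0L, conjugate_length = 0L),
      class = "ft_molecule")
    return(mol)
  }
  # all downstream structure is derived from the canonical string so that the
  # kekule assignment is one fixed, deterministic choice per molecule
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(can)),
                  error = function(e) NULL)
  if (is.null(sdf)) {
    abort(sprintf("invalid SMILES (no structure): %s", text),
          class = "fluortree_invalid_smiles")
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) == 0L) {
    abort(sprintf("invalid SMILES (no atoms): %s", text),
          class = "fluortree_invalid_smiles")
  }
  element <- sub("_[0-9]+$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- .mol_charge(charge_code)

  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  bonds <- if (is.null(bb) || length(bb) == 0L || NROW(bb) == 0L ||
               NCOL(bb) < 3L) {
    tibble(from = integer(0), to = integer(0), order = integer(0))
  } else {
    tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }

  # silent-repair guard: the parser must not have dropped atoms
  n_heavy_tokens <- length(.heavy_atom_tokens(tokens))
  n_heavy <- sum(element != "H")
  if (n_heavy != n_heavy_tokens) {
    abort(sprintf("invalid SMILES (parser repaired the input): %s", text),
          class = "fluortree_invalid_smiles")
  }

  # explicit-valence screen (OpenBabel accepts hypervalent atoms)
  deg <- integer(nrow(ab))
  if (nrow(bonds) > 0L) {
    ord_sum <- tapply(c(bonds$order, bonds$order), c(bonds$from, bonds$to), sum)
    deg[as.integer(names(ord_sum))] <- as.integer(ord_sum)
  }
  maxv <- unname(.max_valence[element])
  maxv[is.na(maxv)] <- 8L
  allow <- maxv + ifelse(element %in% c("N", "O") & charge > 0, charge,
                         ifelse(charge < 0, charge,
                                ifelse(charge > 0, -charge, 0L)))
  if (any(deg > allow)) {
    abort(sprintf("invalid SMILES (valence violation): %s", text),
          class = "fluortree_invalid_smiles")
  }

  if (enforce_elements && !all(element %in% .allowed_elements)) {
    bad <- unique(element[!(element %in% .allowed_elements)])
    abort(sprintf("element(s) outside {H,C,N,O}: %s (in %s)",
                  paste(bad, collapse = ", "), text),
          class = "fluortree_element_error")
  }

  rb <- .ring_basis(sdf, bonds)
  arom_atoms <- unique(unlist(rb$rings[rb$aromatic]))
  atoms <- tibble(element = element,
                  aromatic = seq_along(element) %in% arom_atoms)

  mol <- structure(
    list(smiles_input = text,
         smiles_canonical = can,
         atoms = atoms,
         bonds = bonds,
         ring_basis = rb,
         n_aromatic_rings = sum(rb$aromatic),
         conjugate_length = NA_integer_),
    class = "ft_molecule"
  )
  mol$conjugate_length <- count_conjugate_length(mol)
  mol
}

#' @export
print.ft_molecule <- function(x, ...) {
  cat("<ft_molecule> ", x$smiles_canonical, "\n",
      "  atoms: ", nrow(x$atoms),
      "  aromatic rings: ", x$n_aromatic_rings,
      "  conjugate length: ", x$conjugate_length, "\n", sep = "")
  invisible(x)
}

.as_molecule <- function(mol) {
  if (inherits(mol, "ft_molecule")) mol else parse_smiles(mol)
}

#' Number of aromatic rings
#'
#' Counts the rings of the smallest ring basis whose bonds are all aromatic.
#'
#' @param mol an `ft_molecule` (or a SMILES string, parsed on the fly).
#' @return non-negative integer count.
#' @examples
#' count_aromatic_rings("c1ccc2ccccc2c1") # naphthalene: 2
#' @export
count_aromatic_rings <- function(mol) {
  mol <- .as_molecule(mol)
  as.integer(mol$n_aromatic_rings)
}

#' Conjugation length
#'
#' The conjugation descriptor counts units of the single–double–single bond
#' alternation pattern (one unit per C=C-type double bond). Aromatic systems
#' are kekulized first (one fixed kekule structure per canonical SMILES);
#' the reported value is the maximum number of double bonds along any simple
#' path whose bond orders alternate double/single. A lone double bond counts
#' as 1; triple bonds do not participate.
#'
#' @param mol an `ft_molecule` (or a SMILES string, parsed on the fly).
#' @return non-negative integer count of double-bond units.
#' @examples
#' count_conjugate_length("C=CC=C") # butadiene: 2
#' count_conjugate_length("c1ccccc1") # benzene (kekulized): 3
#' @export
count_conjugate_length <- function(mol) {
  mol <- .as_molecule(mol)
  bonds <- mol$bonds
  bonds <- bonds[bonds$order %in% c(1L, 2L), , drop = FALSE]
  if (!any(bonds$order == 2L)) return(0L)
  n_atom <- nrow(mol$atoms)
  adj <- vector("list", n_atom)
  for (k in seq_len(nrow(bonds))) {
    f <- bonds$from[k]; t <- bonds$to[k]; o <- bonds$order[k]
    adj[[f]] <- rbind(adj[[f]], c(t, o))
    adj[[t]] <- rbind(adj[[t]], c(f, o))
  }
  best <- 0L
  walk <- function(atom, last_order, visited, n_double) {
    if (n_double > best) best <<- n_double
    nb <- adj[[atom]]
    if (is.null(nb)) return(invisible())
    want <- if (last_order == 2L) 1L else 2L
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]; o <- nb[r, 2]
      if (o == want && !visited[nxt]) {
        visited[nxt] <- TRUE
        walk(nxt, o, visited, n_double + (o == 2L))
        visited[nxt] <- FALSE
      }
    }
  }
  starts <- which(bonds$order == 2L)
  for (k in starts) {
    for (ends in list(c(bonds$from[k], bonds$to[k]),
                      c(bonds$to[k], bonds$from[k]))) {
      visited <- logical(n_atom)
      visited[ends] <- TRUE
      walk(ends[2], 2L, visited, 1L)
    }
  }
  as.integer(best)
}

#' Read a SMILES corpus file
#'
#' Plain text, one SMILES per line; blank lines and `#` comment lines are
#' ignored. Strings are returned as-is (not validated).
#'
#' @param path path to the corpus file.
#' @return character vector of SMILES strings.
#' @export
read_smiles_corpus <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("corpus file not found: %s", path),
          class = "fluortree_input_error")
  }
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # a trailing name column (whitespace separated) is tolerated
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
}
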