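# shared fixtures and independent oracles used across the suite

toy_corpus_path <- function() {
  system.file("extdata", "toy_corpus.smi", package = "fluortree")
}

toy_corpus <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- read_smiles_corpus(toy_corpus_path())
    val
  }
})

ref_profiles <- function() {
  readr::read_csv(system.file("extdata", "reference_profiles.csv",
                              package = "fluortree"),
                  col_types = "cdddd")
}

# as a ledger table, in the generation order of the reference listing
ref_ledger <- function() {
  df <- ref_profiles()
  tibble::tibble(generation_index = seq_len(nrow(df)),
                 smiles_canonical = df$species,
                 a_w_nm = df$a_w_nm, a_i = df$a_i,
                 f_w_nm = df$f_w_nm, f_i = df$f_i,
                 reward = NA_real_, status = "ok")
}

# --- independent conjugation-length oracle: exhaustive simple-path ---------
# enumeration with igraph, strict single/double alternation, count doubles
conjugate_length_by_paths <- function(mol) {
  bonds <- mol$bonds[mol$bonds$order %in% c(1L, 2L), , drop = FALSE]
  if (!any(bonds$order == 2L)) return(0L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$from, to = bonds$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  okey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  omap <- stats::setNames(bonds$order, okey(bonds$from, bonds$to))
  best <- 0L
  for (s in seq_len(nrow(mol$atoms))) {
    paths <- igraph::all_simple_paths(g, from = as.character(s))
    for (p in paths) {
      vs <- as.integer(names(p))
      if (length(vs) < 2L) next
      ords <- omap[okey(vs[-length(vs)], vs[-1])]
      if (anyNA(ords)) next
      if (length(ords) > 1L && any(ords[-1] == ords[-length(ords)])) next
      best <- max(best, sum(ords == 2L))
    }
  }
  as.integer(best)
}

# --- independent aromatic-ring-count oracle: cyclomatic number of the ------
# subgraph induced by atoms/bonds of aromatic rings (valid for the fused
# aromatic systems used as fixtures, where every basis ring is aromatic)
aromatic_ring_count_by_cyclomatic <- function(mol) {
  arom_atoms <- which(mol$atoms$aromatic)
  if (length(arom_atoms) == 0L) return(0L)
  b <- mol$bonds[mol$bonds$from %in% arom_atoms & mol$bonds$to %in% arom_atoms, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = b$from, to = b$to), directed = FALSE,
    vertices = data.frame(name = arom_atoms))
  as.integer(igraph::ecount(g) - igraph::vcount(g) +
               igraph::components(g)$no)
}

# --- atom-order randomizer: permutes the atom block of the MOL record and --
# converts back to SMILES, giving alternative writings of the same molecule
randomized_smiles <- function(smiles, n = 20, seed = 1) {
  mol <- parse_smiles(smiles, enforce_elements = FALSE)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(mol$smiles_canonical))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  el <- sub("_[0-9]+$", "", rownames(ab))
  set.seed(seed)
  out <- character(0)
  for (i in seq_len(n)) {
    perm <- sample(nrow(ab))                  # new position j holds old atom perm[j]
    pos <- order(perm)                        # pos[old] = new position
    atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          ab[perm, 1], ab[perm, 2], 0, el[perm])
    bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                          pos[as.integer(bb[, 1])], pos[as.integer(bb[, 2])],
                          as.integer(bb[, 3]))
    mol_txt <- paste(c("", " scrambled", "",
                       sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                               nrow(ab), nrow(bb)),
                       atom_lines, bond_lines, "M  END", "$$$$", ""),
                     collapse = "\n")
    smi <- tryCatch(ChemmineOB::convertFormat("SDF", "SMI", mol_txt),
                    error = function(e) "")
    smi <- sub("[ \t\n\r].*$", "", smi)
    if (nzchar(smi)) out <- c(out, smi)
  }
  unique(out)
}

# --- toy grammar {C, O, =} with content length <= 6: exhaustive ------------
# enumeration of every unique valid molecule and its surrogate reward
toy_grammar_exhaustive <- local({
  val <- NULL
  function() {
    if (!is.null(val)) return(val)
    alphabet <- c("C", "O", "=")
    strs <- unlist(lapply(1:6, function(L) {
      g <- do.call(expand.grid, c(rep(list(alphabet), L),
                                  stringsAsFactors = FALSE))
      apply(g, 1, paste0, collapse = "")
    }))
    params <- reward_params()
    seen <- new.env(parent = emptyenv())
    rewards <- numeric(0)
    smiles <- character(0)
    for (s in strs) {
      m <- tryCatch(parse_smiles(s), error = function(e) NULL)
      if (is.null(m) || !is.null(seen[[m$smiles_canonical]])) next
      seen[[m$smiles_canonical]] <- TRUE
      rewards <- c(rewards, total_reward(surrogate_evaluate(m), params))
      smiles <- c(smiles, m$smiles_canonical)
    }
    val <<- list(smiles = smiles, rewards = rewards, best = max(rewards))
    val
  }
})

toy_grammar_model <- function() {
  corpus <- c("C", "O", "CC", "CO", "C=C", "C=O", "CCO", "C=CC", "OC=O",
              "C=CC=C", "CCC", "OCCO")
  train_prior(corpus, method = "ngram", order = 2, alpha = 1)
}

# gather profiles for n molecules sampled from a prior (duplicates allowed)
sampled_surrogate_records <- function(model, n = 500, seed = 1) {
  set.seed(seed)
  rows <- list()
  tries <- 0L
  while (length(rows) < n && tries < 50L * n) {
    tries <- tries + 1L
    comp <- sample_completion(model, max_len = 40)
    if (!comp$terminated) next
    mol <- tryCatch(parse_smiles(comp$smiles), error = function(e) NULL)
    if (is.null(mol)) next
    pr <- surrogate_evaluate(mol)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      generation_index = length(rows) + 1L,
      smiles_canonical = mol$smiles_canonical,
      a_w_nm = pr$a_w, a_i = pr$a_i, f_w_nm = pr$f_w, f_i = pr$f_i,
      reward = total_reward(pr), status = "ok",
      n_aromatic_rings = mol$n_aromatic_rings,
      conjugate_length = mol$conjugate_length)
  }
  dplyr::bind_rows(rows)
}
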