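#' Search configuration
#'
#' @param budget number of completed oracle evaluations of valid, previously
#'   unseen molecules to collect before stopping.
#' @param C exploration constant of the selection score (default 4).
#' @param n_workers number of concurrently in-flight rollouts. The
#'   coordinator owns the tree: it selects `n_workers` leaves under virtual
#'   loss, evaluates them, then backpropagates — tree mutation is fully
#'   serialized, evaluation is batched.
#' @param max_len maximum rollout length in tokens (begin sentinel
#'   included).
#' @param seed integer seed; single-worker runs are bit-reproducible.
#' @param prior_floor children whose prior falls below this are pruned at
#'   expansion (the retained mass is renormalized).
#' @param max_rollouts hard cap on rollouts, protecting against grammars too
#'   small to ever meet `budget`.
#' @param stall_limit stop after this many consecutive rollouts that produce
#'   no new unique molecule (exhausted search space).
#' @param enforce_elements restrict rollout molecules to H/C/N/O.
#' @return an object of class `ft_search_config`.
#' @export
search_config <- function(budget = 100, C = 4, n_workers = 1, max_len = 82,
                          seed = 1, prior_floor = 1e-4,
                          max_rollouts = 60 * budget,
                          stall_limit = max_rollouts,
                          enforce_elements = TRUE) {
  if (budget < 1) abort("budget must be at least 1", class = "fluortree_input_error")
  if (C <= 0) abort("C must be positive", class = "fluortree_config_error")
  if (n_workers < 1) abort("n_workers must be at least 1", class = "fluortree_config_error")
  structure(list(budget = as.integer(budget), C = C,
                 n_workers = as.integer(n_workers),
                 max_len = as.integer(max_len), seed = as.integer(seed),
                 prior_floor = prior_floor,
                 max_rollouts = as.integer(max_rollouts),
                 stall_limit = as.integer(stall_limit),
                 enforce_elements = isTRUE(enforce_elements)),
            class = "ft_search_config")
}

#' Virtual-loss selection score
#'
#' The PUCT-style score used to pick a child during selection:
#' \deqn{S_i = \frac{R_i}{v_i + w_i} +
#'       C P_i \frac{\sqrt{v_p + w_p}}{1 + v_i + w_i}}
#' where \eqn{R_i} is the child's cumulative reward, \eqn{v_i} its completed
#' visits, \eqn{w_i} its virtual (in-flight) visits and \eqn{P_i} its prior.
#' For an unvisited child (\eqn{v_i + w_i = 0}) the exploitation term is 0,
#' so the prior drives first visits. Virtual visits enlarge both
#' denominators, which is what spreads concurrent selections across the
#' tree.
#'
#' @param R,v,w,P child statistics (vectorized).
#' @param v_p,w_p parent completed and virtual visit counts.
#' @param C exploration constant.
#' @return numeric score vector.
#' @examples
#' selection_score(R = 1, v = 1, w = 0, P = 0.5, v_p = 1, w_p = 0, C = 4)
#' @export
selection_score <- function(R, v, w, P, v_p, w_p, C = 4) {
  n <- v + w
  exploit <- ifelse(n == 0, 0, R / n)
  exploit + C * P * sqrt(v_p + w_p) / (1 + n)
}

.new_node <- function(token_id, prefix, P, terminal = FALSE) {
  e <- new.env(parent = emptyenv())
  e$token_id <- token_id
  e$prefix <- prefix
  e$R <- 0
  e$v <- 0L
  e$w <- 0L
  e$P <- P
  e$children <- NULL
  e$terminal <- terminal
  class(e) <- "ft_node"
  e
}

#' Create a search tree root
#'
#' @param vocab an [smiles_vocabulary()].
#' @return the root `ft_node` (prefix = the begin sentinel).
#' @export
new_search_tree <- function(vocab) {
  stopifnot(inherits(vocab, "ft_vocab"))
  root <- .new_node(1L, 1L, P = 1)
  attr(root, "vocab") <- vocab
  root
}

#' @export
print.ft_node <- function(x, ...) {
  cat(sprintf("<ft_node> depth %d | R=%.3f v=%d w=%d P=%.4f | %s\n",
              length(x$prefix) - 1L, x$R, x$v, x$w, x$P,
              if (is.null(x$children)) "unexpanded"
              else paste(length(x$children), "children")))
  invisible(x)
}

#' Expand a node over the token vocabulary
#'
#' Creates one child per vocabulary token carrying the language-model prior
#' for the node's prefix. Children with prior below `prior_floor` are
#' pruned and the retained mass renormalized; the begin sentinel is never a
#' child. Terminal nodes cannot be expanded.
#'
#' @param node an `ft_node`.
#' @param model an [train_prior()] model.
#' @param prior_floor pruning threshold on the raw prior.
#' @param max_len prefix length (tokens) at which children are terminal.
#' @return the node, invisibly (children attached in vocabulary order).
#' @export
expand_node <- function(node, model, prior_floor = 1e-4, max_len = 82) {
  stopifnot(inherits(node, "ft_node"), inherits(model, "ft_prior"))
  if (node$terminal) {
    abort("cannot expand a terminal node", class = "fluortree_expand_error")
  }
  if (!is.null(node$children)) {
    abort("node is already expanded", class = "fluortree_expand_error")
  }
  vocab <- model$vocab
  p <- next_token_distribution(model, vocab$tokens[node$prefix])
  begin_id <- match(vocab$begin_token, vocab$tokens)
  keep <- setdiff(which(p >= prior_floor), begin_id)
  if (length(keep) == 0L) keep <- setdiff(order(p, decreasing = TRUE),
                                          begin_id)[1]
  pk <- p[keep] / sum(p[keep])
  end_id <- match(vocab$end_token, vocab$tokens)
  child_len <- length(node$prefix) + 1L
  node$children <- lapply(seq_along(keep), function(j) {
    tid <- keep[j]
    .new_node(tid, c(node$prefix, tid), unname(pk[j]),
              terminal = (tid == end_id || child_len >= max_len))
  })
  invisible(node)
}

#' Select a leaf under virtual loss
#'
#' Descends from the root by argmax of [selection_score()], breaking ties
#' toward the lowest vocabulary index, until reaching an unexpanded or
#' terminal node. A virtual visit is added to every node on the path as it
#' is selected, so a second selection made before backpropagation is
#' diverted to a different part of the tree.
#'
#' @param root an `ft_node` tree root.
#' @param C exploration constant.
#' @return list of `ft_node` from root to the selected leaf.
#' @export
select_leaf <- function(root, C = 4) {
  node <- root
  node$w <- node$w + 1L
  path <- list(node)
  while (!is.null(node$children) && length(node$children) > 0L &&
         !node$terminal) {
    scores <- vapply(node$children, function(ch) {
      selection_score(ch$R, ch$v, ch$w, ch$P, node$v, node$w, C)
    }, numeric(1))
    node <- node$children[[which.max(scores)]]
    node$w <- node$w + 1L
    path <- c(path, list(node))
  }
  path
}

#' Backpropagate a rollout reward
#'
#' Adds the reward and one completed visit to every node on the path and
#' removes the virtual visit placed there by [select_leaf()].
#'
#' @param path list of `ft_node` (root first).
#' @param reward score in `[0, 1]`.
#' @return invisibly, `path`.
#' @export
backpropagate <- function(path, reward) {
  if (!is.numeric(reward) || is.na(reward) || reward < 0 || reward > 1) {
    abort("reward must lie in [0, 1]", class = "fluortree_input_error")
  }
  for (node in path) {
    if (node$w < 1L) {
      abort("virtual-visit underflow: node has no in-flight selection",
            class = "fluortree_state_error")
    }
  }
  for (node in path) {
    node$R <- node$R + reward
    node$v <- node$v + 1L
    node$w <- node$w - 1L
  }
  invisible(path)
}

#' Complete, validate and score one rollout
#'
#' Samples a completion of the prefix from the prior, validates it as a
#' molecule, evaluates the oracle and computes the total reward. Invalid
#' strings and failed evaluations yield reward 0.
#'
#' @param model an [train_prior()] model.
#' @param prefix character token vector (leading begin sentinel optional).
#' @param oracle an [make_oracle()] evaluator.
#' @param params an [reward_params()].
#' @param max_len rollout length cap in tokens.
#' @param enforce_elements restrict to H/C/N/O.
#' @param cache optional [oracle_cache()].
#' @return list with `smiles`, `valid`, `molecule` (or `NULL`), `profile`
#'   (or `NULL`) and `reward`.
#' @export
rollout_candidate <- function(model, prefix, oracle, params = reward_params(),
                              max_len = 82, enforce_elements = TRUE,
                              cache = NULL) {
  comp <- sample_completion(model, prefix, max_len = max_len)
  smiles <- comp$smiles
  if (!comp$terminated || !nzchar(smiles)) {
    return(list(smiles = smiles, valid = FALSE, molecule = NULL,
                profile = NULL, reward = 0))
  }
  mol <- tryCatch(parse_smiles(smiles, enforce_elements = enforce_elements),
                  error = function(e) NULL)
  if (is.null(mol)) {
    return(list(smiles = smiles, valid = FALSE, molecule = NULL,
                profile = NULL, reward = 0))
  }
  profile <- oracle_evaluate(mol, oracle, cache)
  list(smiles = smiles, valid = TRUE, molecule = mol, profile = profile,
       reward = total_reward(profile, params))
}

.ledger_row <- function(idx, mol, profile, reward) {
  ok <- profile$status == "ok"
  tibble(
    generation_index = idx,
    smiles_canonical = mol$smiles_canonical,
    a_w_nm = if (ok) profile$a_w else NA_real_,
    a_i = if (ok) profile$a_i else NA_real_,
    f_w_nm = if (ok) profile$f_w else NA_real_,
    f_i = if (ok) profile$f_i else NA_real_,
    reward = reward,
    status = profile$status,
    n_aromatic_rings = mol$n_aromatic_rings,
    conjugate_length = mol$conjugate_length
  )
}

#' Monte Carlo tree search over SMILES tokens
#'
#' Runs the select / expand / rollout / backpropagate loop until `budget`
#' valid, unique molecules have been evaluated (or the rollout cap is hit).
#' With `n_workers > 1`, that many selections are made under virtual loss
#' before any of their rewards is backpropagated, emulating in-flight
#' parallel evaluation while the coordinator retains sole ownership of the
#' tree. Duplicate molecules (same canonical SMILES) are served from the
#' evaluation cache and never get a second generation index; invalid
#' rollouts backpropagate reward 0 so the tree learns to avoid them, but do
#' not consume budget.
#'
#' @param model an [train_prior()] model.
#' @param oracle an [make_oracle()] evaluator (see [surrogate_oracle()]).
#' @param params an [reward_params()].
#' @param config an [search_config()].
#' @return an object of class `ft_search`: `ledger` (tibble, one row per
#'   unique molecule in generation order), `root` (the search tree),
#'   `config`, plus rollout accounting. Use [tidy()] / [glance()] /
#'   [autoplot()][ggplot2::autoplot] on it.
#' @export
mcts_search <- function(model, oracle, params = reward_params(),
                        config = search_config()) {
  stopifnot(inherits(model, "ft_prior"), inherits(oracle, "ft_oracle"),
            inherits(params, "ft_reward_params"),
            inherits(config, "ft_search_config"))
  vocab <- model$vocab
  set.seed(config$seed)
  root <- new_search_tree(vocab)
  cache <- oracle_cache()
  seen <- new.env(parent = emptyenv())      # canonical smiles -> gen index
  memo <- new.env(parent = emptyenv())      # raw completion -> reward/key
  rows <- vector("list", config$budget)
  completed <- 0L
  rollouts <- 0L
  n_invalid <- 0L
  n_duplicate <- 0L
  stall <- 0L

  do_rollout <- function(leaf) {
    prefix <- vocab$tokens[leaf$prefix]
    comp <- sample_completion(model, prefix, max_len = config$max_len)
    key <- paste0("s:", comp$smiles, if (!comp$terminated) "\r!")
    hit <- memo[[key]]
    if (!is.null(hit)) {
      if (!is.na(hit$canonical)) n_duplicate <<- n_duplicate + 1L
      else n_invalid <<- n_invalid + 1L
      return(hit$reward)
    }
    if (!comp$terminated || !nzchar(comp$smiles)) {
      n_invalid <<- n_invalid + 1L
      memo[[key]] <- list(reward = 0, canonical = NA_character_)
      return(0)
    }
    mol <- tryCatch(parse_smiles(comp$smiles,
                                 enforce_elements = config$enforce_elements),
                    error = function(e) NULL)
    if (is.null(mol)) {
      n_invalid <<- n_invalid + 1L
      memo[[key]] <- list(reward = 0, canonical = NA_character_)
      return(0)
    }
    can <- mol$smiles_canonical
    if (!is.null(seen[[can]])) {
      # duplicate via a different raw string: cached profile, no new index
      n_duplicate <<- n_duplicate + 1L
      reward <- total_reward(oracle_evaluate(mol, oracle, cache), params)
      memo[[key]] <- list(reward = reward, canonical = can)
      return(reward)
    }
    profile <- oracle_evaluate(mol, oracle, cache)
    reward <- total_reward(profile, params)
    completed <<- completed + 1L
    seen[[can]] <- completed
    rows[[completed]] <<- .ledger_row(completed, mol, profile, reward)
    stall <<- -1L                            # progress: reset stall counter
    memo[[key]] <- list(reward = reward, canonical = can)
    reward
  }

  while (completed < config$budget && rollouts < config$max_rollouts &&
         stall < config$stall_limit) {
    n_batch <- min(config$n_workers, config$budget)
    paths <- vector("list", n_batch)
    for (k in seq_len(n_batch)) {
      path <- select_leaf(root, config$C)
      leaf <- path[[length(path)]]
      if (!leaf$terminal && is.null(leaf$children)) {
        expand_node(leaf, model, prior_floor = config$prior_floor,
                    max_len = config$max_len)
      }
      paths[[k]] <- path
    }
    for (path in paths) {
      if (completed >= config$budget) {
        # budget met mid-batch: release the virtual loss without a visit
        for (node in path) node$w <- node$w - 1L
        next
      }
      leaf <- path[[length(path)]]
      reward <- do_rollout(leaf)
      backpropagate(path, reward)
      rollouts <- rollouts + 1L
      stall <- stall + 1L
    }
  }

  ledger <- dplyr::bind_rows(rows[seq_len(completed)])
  structure(
    list(ledger = ledger, root = root, config = config,
         oracle_name = oracle$name, prior_method = model$method,
         n_rollouts = rollouts, n_invalid = n_invalid,
         n_duplicate = n_duplicate, n_oracle_evals = n_evals(cache)),
    class = "ft_search")
}

#' @export
print.ft_search <- function(x, ...) {
  cat("<ft_search> ", nrow(x$ledger), " unique molecules from ",
      x$n_rollouts, " rollouts (", x$n_invalid, " invalid, ",
      x$n_duplicate, " duplicates)\n", sep = "")
  if (nrow(x$ledger) > 0L) {
    best <- x$ledger[which.max(x$ledger$reward), ]
    cat(sprintf("  best reward %.4f: %s\n", best$reward,
                best$smiles_canonical))
  }
  invisible(x)
}

#' Tidy a search result
#'
#' @param x an `ft_search` object.
#' @param ... unused.
#' @return `tidy()`: the run ledger, one row per unique generated molecule.
#'   `glance()`: a one-row run summary.
#' @method tidy ft_search
#' @export
tidy.ft_search <- function(x, ...) x$ledger

#' @rdname tidy.ft_search
#' @method glance ft_search
#' @export
glance.ft_search <- function(x, ...) {
  tibble(
    n_generated = nrow(x$ledger),
    n_rollouts = x$n_rollouts,
    n_invalid = x$n_invalid,
    n_duplicate = x$n_duplicate,
    best_reward = if (nrow(x$ledger)) max(x$ledger$reward) else NA_real_,
    mean_reward = if (nrow(x$ledger)) mean(x$ledger$reward) else NA_real_,
    seed = x$config$seed,
    n_workers = x$config$n_workers
  )
}

#' Read / write a run ledger CSV
#'
#' The on-disk schema is fixed: `generation_index, smiles_canonical, a_w_nm,
#' a_i, f_w_nm, f_i, reward, status`. The in-memory ledger's structural
#' descriptor columns are recomputed on read when needed.
#'
#' @param ledger ledger tibble (from `tidy()` on an `ft_search`).
#' @param path CSV path.
#' @return `read_ledger` returns a tibble; `write_ledger` returns `path`
#'   invisibly.
#' @export
write_ledger <- function(ledger, path) {
  cols <- c("generation_index", "smiles_canonical", "a_w_nm", "a_i",
            "f_w_nm", "f_i", "reward", "status")
  readr::write_csv(ledger[, cols], path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("ledger not found: %s", path),
          class = "fluortree_input_error")
  }
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      generation_index = readr::col_integer(),
      smiles_canonical = readr::col_character(),
      a_w_nm = readr::col_double(), a_i = readr::col_double(),
      f_w_nm = readr::col_double(), f_i = readr::col_double(),
      reward = readr::col_double(), status = readr::col_character()
    )))
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed ledger row(s) at line %s of %s",
                  paste(unique(probs$row + 1L), collapse = ", "), path),
          class = "fluortree_parse_error")
  }
  df
}
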