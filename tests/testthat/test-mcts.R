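test_that("the selection score matches hand-evaluated cases", {
  expect_equal(selection_score(R = 1, v = 1, w = 0, P = 0.5,
                               v_p = 1, w_p = 0, C = 4),
               2, tolerance = 1e-9)
  expect_equal(selection_score(R = 1, v = 1, w = 1, P = 0.5,
                               v_p = 1, w_p = 1, C = 4),
               0.5 + 4 * 0.5 * sqrt(2) / 3, tolerance = 1e-9)
  # unvisited convention: exploitation term is 0, prior drives the visit
  expect_equal(selection_score(R = 0, v = 0, w = 0, P = 0.3,
                               v_p = 5, w_p = 2, C = 4),
               4 * 0.3 * sqrt(7), tolerance = 1e-12)
})

test_that("the score strictly decreases in the virtual-visit count", {
  set.seed(17)
  for (i in 1:50) {
    v <- sample(0:20, 1); R <- runif(1) * v; P <- runif(1)
    v_p <- sample(1:50, 1); w_p <- sample(0:10, 1); C <- runif(1, 0.5, 8)
    s <- selection_score(R, v, w = 0:6, P, v_p, w_p, C)
    expect_true(all(diff(s) < 0))
  }
})

test_that("selection follows argmax, breaks ties low, and diverts under virtual loss", {
  model <- toy_grammar_model()
  vocab <- model$vocab
  root <- new_search_tree(vocab)
  expand_node(root, model, prior_floor = 0)
  # equal stats across children: tie broken toward the lowest vocabulary index
  for (ch in root$children) { ch$R <- 1; ch$v <- 2L; ch$P <- 0.2 }
  root$v <- length(root$children) * 2L
  p1 <- select_leaf(root, C = 4)
  expect_identical(p1[[2]]$token_id, root$children[[1]]$token_id)
  # no backpropagation yet: the second selection must take a different child
  p2 <- select_leaf(root, C = 4)
  expect_false(identical(p2[[2]], p1[[2]]))
  # virtual visits sit on both paths until backpropagation clears them
  expect_identical(root$w, 2L)
  backpropagate(p1, 0.5)
  backpropagate(p2, 0.25)
  expect_identical(root$w, 0L)
  expect_identical(root$v, length(root$children) * 2L + 2L)
})

test_that("expansion prunes tiny priors and refuses terminal nodes", {
  model <- toy_grammar_model()
  root <- new_search_tree(model$vocab)
  expand_node(root, model, prior_floor = 1e-4)
  p <- vapply(root$children, function(ch) ch$P, numeric(1))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  raw <- next_token_distribution(model)
  kept <- model$vocab$tokens[vapply(root$children, function(ch) ch$token_id,
                                    integer(1))]
  expect_gte(sum(raw[kept]) / sum(raw), 0.999)
  # the begin sentinel is never a child
  expect_false(model$vocab$begin_token %in% kept)
  expect_error(expand_node(root, model), class = "fluortree_expand_error")
  end_child <- Filter(function(ch) ch$terminal, root$children)[[1]]
  expect_error(expand_node(end_child, model), class = "fluortree_expand_error")
  # a degenerate model concentrates the prior on its first token
  ccomodel <- train_prior(rep("CCO", 50))
  r2 <- new_search_tree(ccomodel$vocab)
  expand_node(r2, ccomodel)
  top <- r2$children[[which.max(vapply(r2$children, function(ch) ch$P,
                                       numeric(1)))]]
  expect_identical(ccomodel$vocab$tokens[top$token_id], "C")
})

test_that("backpropagation guards its invariants", {
  model <- toy_grammar_model()
  root <- new_search_tree(model$vocab)
  expand_node(root, model)
  path <- select_leaf(root, 4)
  expect_error(backpropagate(path, 1.5), class = "fluortree_input_error")
  backpropagate(path, 0.5)
  expect_error(backpropagate(path, 0.5), class = "fluortree_state_error")
  for (node in path) expect_identical(node$w, 0L)
})

test_that("rollouts score valid completions and zero out invalid ones", {
  model <- toy_grammar_model()
  params <- reward_params()
  # force the exact completion by handing the full string plus end token
  toks <- c(tokenize_smiles("C=CC=C", model$vocab), model$vocab$end_token)
  r <- rollout_candidate(model, toks, surrogate_oracle(), params)
  expect_true(r$valid)
  expect_equal(r$reward,
               total_reward(surrogate_evaluate(parse_smiles("C=CC=C")), params),
               tolerance = 1e-12)
  # an unterminated prefix at max_len is invalid
  set.seed(1)
  bad <- rollout_candidate(model, c("C", "="), surrogate_oracle(), params,
                           max_len = 3)
  expect_false(bad$valid)
  expect_identical(bad$reward, 0)
})

test_that("single-worker search is deterministic and its ledger is sound", {
  model <- toy_grammar_model()
  cfg <- search_config(budget = 40, seed = 5, max_len = 8)
  r1 <- mcts_search(model, surrogate_oracle(), reward_params(), cfg)
  r2 <- mcts_search(model, surrogate_oracle(), reward_params(), cfg)
  expect_identical(r1$ledger, r2$ledger)
  led <- tidy(r1)
  expect_false(any(duplicated(led$smiles_canonical)))
  expect_identical(led$generation_index, seq_len(nrow(led)))
  expect_true(all(led$reward >= 0 & led$reward <= 1))
  # visit conservation: the root records one completed visit per rollout,
  # and no virtual visits remain after quiescence
  expect_identical(r1$root$v, r1$n_rollouts)
  all_w_zero <- function(node) {
    node$w == 0L && all(vapply(node$children %||% list(), all_w_zero,
                               logical(1)))
  }
  expect_true(all_w_zero(r1$root))
  child_v <- sum(vapply(r1$root$children, function(ch) ch$v, integer(1)))
  expect_gte(r1$root$v, child_v)
  expect_error(search_config(budget = 0), class = "fluortree_input_error")
})

test_that("ledger CSV round-trips and rejects malformed rows", {
  model <- toy_grammar_model()
  res <- mcts_search(model, surrogate_oracle(), reward_params(),
                     search_config(budget = 15, seed = 2, max_len = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(tidy(res), path)
  back <- read_ledger(path)
  expect_identical(back$smiles_canonical, res$ledger$smiles_canonical)
  expect_equal(back$reward, res$ledger$reward, tolerance = 1e-12)
  lines <- readLines(path)
  lines[3] <- sub("^([^,]*,[^,]*,)[0-9.]+", "\\1not_a_number", lines[3])
  writeLines(lines, path)
  err <- expect_error(read_ledger(path), class = "fluortree_parse_error")
  expect_match(conditionMessage(err), "at line [0-9]+")
})
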