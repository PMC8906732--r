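test_that("the three-part photophysical filter reproduces the reference verdicts", {
  ref <- ref_profiles()
  verdicts <- lapply(seq_len(nrow(ref)), function(i) {
    passes_filter(photophysical_profile(ref$a_w_nm[i], ref$a_i[i],
                                        ref$f_w_nm[i], ref$f_i[i]))
  })
  names(verdicts) <- ref$species
  expect_true(verdicts$PC$pass)
  expect_true(verdicts$PC1$pass)
  expect_true(verdicts$PC3$pass)
  # the weakly absorbing isomer fails only the absorption-strength criterion
  expect_false(verdicts$PC2$pass)
  expect_identical(verdicts$PC2$failed, "abs_os")
  # the planar coumarin fails only the Stokes-shift criterion (53 nm < 100)
  expect_false(verdicts$V$pass)
  expect_identical(verdicts$V$failed, "shift")
})

test_that("filtering a ledger preserves order and reports percentages", {
  res <- filter_candidates(ref_ledger())
  expect_identical(res$passed$smiles_canonical, c("PC", "PC1", "PC3"))
  expect_identical(res$summary$n_pass, 3L)
  expect_equal(res$summary$pct_pass, 60)
  expect_equal(pass_rate_pct(87, 3643), 2.39)
  expect_equal(pass_rate_pct(4, 661), 0.61)
  expect_equal(pass_rate_pct(0, 100), 0)
  expect_equal(pass_rate_pct(0, 0), 0)
  expect_error(filter_candidates(ref_ledger()[0, ]),
               class = "fluortree_input_error")
  # failed evaluations are filter-inapplicable one by one ...
  expect_error(passes_filter(photophysical_profile(status = "evaluation_failed")),
               class = "fluortree_filter_error")
  # ... and never pass inside a ledger
  led <- ref_ledger()
  led$status[1] <- "evaluation_failed"
  res2 <- filter_candidates(led)
  expect_identical(res2$passed$smiles_canonical, c("PC1", "PC3"))
  expect_identical(res2$report$failed_criteria[1], "evaluation_failed")
})

test_that("the strictness flag decides boundary cases, never silently", {
  boundary <- photophysical_profile(400, 0.1, 500, 0.05)  # a_i exactly at 0.1
  expect_false(passes_filter(boundary, filter_criteria(strict = TRUE))$pass)
  expect_true(passes_filter(boundary, filter_criteria(strict = FALSE))$pass)
})

test_that("the filter is monotone in its thresholds", {
  set.seed(7)
  led <- ref_ledger()[rep(1:5, 20), ]
  led$a_i <- runif(100, 0, 0.4); led$f_w_nm <- runif(100, 300, 900)
  led$f_i <- runif(100, 0, 0.2); led$a_w_nm <- led$f_w_nm - runif(100, 0, 300)
  base <- filter_candidates(led)$summary$n_pass
  for (arg in list(list(min_abs_os = 0.2), list(min_fl_wavelength = 500),
                   list(min_fl_os = 0.05), list(min_shift = 150))) {
    tighter <- filter_candidates(led, do.call(filter_criteria, arg))
    expect_lte(tighter$summary$n_pass, base)
  }
})

test_that("pearson_correlation matches direct summation and guards its domain", {
  expect_equal(pearson_correlation(1:3, 1:3), 1)
  expect_equal(pearson_correlation(1:3, 3:1), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  hand <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), hand, tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3),
               class = "fluortree_correlation_error")
  expect_error(pearson_correlation(1:2, 1:2), class = "fluortree_input_error")
})

test_that("the correlation table recovers the surrogate's built-in dependencies", {
  # acyclic polyene records: a_w is exactly linear in conjugation length
  polyenes <- c("C=C", "C=CC=C", "C=CC=CC=C", "C=CC=CC=CC=C", "CC=CC", "C=O")
  rows <- lapply(seq_along(polyenes), function(i) {
    mol <- parse_smiles(polyenes[i])
    pr <- surrogate_evaluate(mol)
    tibble::tibble(generation_index = i, smiles_canonical = mol$smiles_canonical,
                   a_w_nm = pr$a_w, a_i = pr$a_i, f_w_nm = pr$f_w, f_i = pr$f_i,
                   reward = total_reward(pr), status = "ok",
                   n_aromatic_rings = mol$n_aromatic_rings,
                   conjugate_length = mol$conjugate_length)
  })
  led <- dplyr::bind_rows(rows)
  tab <- correlation_table(dplyr::mutate(led,
                                         n_aromatic_rings = n_aromatic_rings +
                                           c(1L, 0L, 1L, 0L, 1L, 0L)))
  # ^ jitter the (constant) ring column only so that its correlations exist
  expect_identical(dim(tab), c(2L, 5L))
  conj <- tab[tab$descriptor == "conjugate_length", ]
  expect_equal(conj$a_w_nm, 1, tolerance = 1e-9)
  expect_gt(conj$a_i, 0.9)
  # constant profiles have no defined correlation
  flat <- led; flat$a_w_nm <- 300
  expect_error(correlation_table(flat), class = "fluortree_correlation_error")
})

test_that("shuffled pairings destroy the structure-property association", {
  model <- train_prior(toy_corpus())
  led <- sampled_surrogate_records(model, n = 500, seed = 21)
  set.seed(22)
  led$a_w_nm <- sample(led$a_w_nm)
  tab <- correlation_table(led)
  expect_lt(abs(tab$a_w_nm[tab$descriptor == "conjugate_length"]), 0.2)
})

test_that("run summaries use the lower median and conserve bin counts", {
  mols <- c("C", "CC", "CCO", "C=C", "C=CC=C", "c1ccccc1", "c1ccncc1",
            "C=Cc1ccccc1", "CC(=O)C", "OC=O")
  led <- dplyr::bind_rows(lapply(seq_along(mols), function(i) {
    mol <- parse_smiles(mols[i])
    pr <- surrogate_evaluate(mol)
    tibble::tibble(generation_index = i,
                   smiles_canonical = mol$smiles_canonical,
                   a_w_nm = pr$a_w, a_i = pr$a_i, f_w_nm = pr$f_w,
                   f_i = pr$f_i, reward = total_reward(pr), status = "ok")
  }))
  sub <- led[c(2, 5, 9), ]
  s <- summarize_run(led, sub)
  expect_identical(s$median_generation_index, 5L)
  expect_equal(s$pct_pass, 30)
  s_all <- summarize_run(led, led)
  expect_identical(s_all$median_generation_index, 5L)   # lower median of 1..10
  expect_identical(sum(s$distributions$count), 2L * nrow(led))
  s_none <- summarize_run(led, led[0, ])
  expect_false(s_none$median_defined)
  expect_true(is.na(s_none$median_generation_index))
  expect_error(summarize_run(led, ref_ledger()[1, ] |>
                               dplyr::mutate(smiles_canonical = "ZZZ")),
               class = "fluortree_input_error")
})

test_that("reported percentages round back to the pass count", {
  set.seed(12)
  for (i in 1:20) {
    total <- sample(50:5000, 1)
    pass <- sample(0:total, 1)
    pct <- pass_rate_pct(pass, total)
    expect_lte(abs(pct * total / 100 - pass), 0.5)
  }
})
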