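make_shift_dataset <- function(seed = 9) {
  sh <- simulate_with_shift(bd_params(0.02, 0.2), bd_params(0.1, 0.2),
                            shift_age = 60, crown_age = 100, seed = seed)
  col <- collapse_to_higher_taxa(sh$recon, 20, mark_tips = sh$true_tips)
  true_labs <- col$truth$label[col$truth$marked]
  list(rt = col$rt, true_labs = true_labs)
}

test_that("the homogeneous model has two parameters and a consistent AIC", {
  d <- make_shift_dataset()
  m0 <- fit_homogeneous(d$rt)
  expect_equal(m0$k, 2L)
  expect_equal(m0$AIC, 2 * 2 - 2 * m0$lnL)
  expect_length(m0$shift_nodes, 0)
  # tiny trees fit but are flagged
  m2 <- fit_homogeneous(toy_rt("(A:10,B:10);", c(A = 5, B = 80)))
  expect_true("low_information" %in% m2$flags)
})

test_that("a shift at the root is equivalent to refitting the homogeneous model", {
  d <- make_shift_dataset()
  m0 <- fit_homogeneous(d$rt)
  root <- d$rt$chronogram$n_tip + 1L
  cand <- try_shift(d$rt, m0, root)
  expect_equal(cand$lnL, m0$lnL, tolerance = 1e-6)
  expect_equal(cand$k, 5L)
})

test_that("try_shift at the true node beats wrong placements", {
  d <- make_shift_dataset()
  rt <- d$rt
  m0 <- fit_homogeneous(rt)
  true_node <- resolve_clade(rt, d$true_labs)
  cand_true <- try_shift(rt, m0, true_node, scan = FALSE)
  expect_false(is.null(cand_true))
  # against a handful of disjoint wrong clades
  set.seed(1)
  phy <- rt$chronogram$phy
  n <- rt$chronogram$n_tip
  comp <- setdiff(phy$tip.label, d$true_labs)
  wrong <- setdiff((n + 2L):(n + phy$Nnode), c(true_node))
  wrong <- wrong[!vapply(wrong, function(v) true_node %in% .ancestors_of(phy, v) ||
                           v %in% .ancestors_of(phy, true_node) ||
                           setequal(clade_tips(rt, v), comp), TRUE)]
  wrong <- sample(wrong, min(5, length(wrong)))
  for (w in wrong) {
    cw <- try_shift(rt, m0, w, scan = FALSE)
    if (!is.null(cw)) expect_gt(cand_true$lnL, cw$lnL)
  }
})

test_that("stepwise search recovers an engineered shift and keeps its invariants", {
  d <- make_shift_dataset(seed = 9)
  models <- stepwise_search(d$rt)
  final <- models[[length(models)]]
  expect_gte(length(final$shift_nodes), 1L)
  # AIC bookkeeping: k = 2 + 3s, AIC = 2k - 2 lnL, for every emitted model
  for (m in models) {
    expect_equal(m$k, 2L + 3L * length(m$shift_nodes))
    expect_equal(m$AIC, 2 * m$k - 2 * m$lnL, tolerance = 1e-12)
  }
  # lnL nondecreasing along the accepted sequence
  lnls <- vapply(models, `[[`, 0, "lnL")
  expect_true(all(diff(lnls) > -1e-8))
  # the first accepted shift is the true clade (or its parent/child)
  truek <- clade_key(d$rt, resolve_clade(d$rt, d$true_labs))
  phy <- d$rt$chronogram$phy
  tn <- resolve_clade(d$rt, d$true_labs)
  near <- c(phy$edge[phy$edge[, 2] == tn, 1], phy$edge[phy$edge[, 1] == tn, 2])
  ok_keys <- vapply(c(tn, near), function(v) clade_key(d$rt, v), "")
  expect_true(clade_key(d$rt, final$shift_nodes[1]) %in% ok_keys)
  # regimes partition the tree
  expect_true(all(final$assignment >= 1 & final$assignment <= length(final$params)))
  expect_equal(sum(final$regimes$n_edges), nrow(d$rt$edges))
})

test_that("search results do not depend on internal node numbering", {
  d <- make_shift_dataset(seed = 12)
  rt1 <- d$rt
  # rewrite the same tree with rotated clades; canonical tie-break keeps the
  # recovered shift leafsets identical
  txt <- ape::write.tree(ape::rotateConstr(rt1$chronogram$phy,
                                           rev(rt1$chronogram$phy$tip.label)))
  ch2 <- as_chronogram(ape::read.tree(text = txt))
  rt2 <- suppressMessages(richness_tree(ch2, richness_table(names(rt1$richness),
                                                            unname(rt1$richness))))
  f1 <- stepwise_search(rt1)
  f2 <- stepwise_search(rt2)
  k1 <- vapply(f1[[length(f1)]]$shift_nodes, function(v) clade_key(rt1, v), "")
  k2 <- vapply(f2[[length(f2)]]$shift_nodes, function(v) clade_key(rt2, v), "")
  expect_identical(sort(k1), sort(k2))
})

test_that("shift direction follows the richness ratio", {
  d <- make_shift_dataset(seed = 9)
  models <- stepwise_search(d$rt, max_shifts = 1)
  final <- models[[length(models)]]
  v <- final$shift_nodes[1]
  rr <- richness_ratio(final, v)
  expect_identical(classify_direction(final, v), if (rr$ratio > 1) "up" else "down")
})

test_that("shift-model JSON reports carry leafsets, rates and AIC", {
  d <- make_shift_dataset(seed = 9)
  models <- stepwise_search(d$rt, max_shifts = 1)
  final <- models[[length(models)]]
  rep <- shift_model_report(final)
  expect_equal(rep$n_shifts, length(final$shift_nodes))
  expect_equal(rep$AIC, final$AIC)
  tf <- tempfile(fileext = ".json")
  write_shift_model_json(final, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$n_shifts, rep$n_shifts)
  expect_equal(length(back$regimes), length(final$params))
  unlink(tf)
})
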