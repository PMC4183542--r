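test_that("transient probabilities match closed forms and boundaries", {
  p <- bd_params(0.1, 0)
  tr0 <- bd_transients(0, p)
  expect_equal(tr0$beta, 0)
  expect_equal(tr0$alpha, 0)
  expect_equal(tr0$p_survival, 1)
  expect_equal(bd_transients(10, p)$beta, 1 - exp(-1), tolerance = 1e-12)
  # with extinction: alpha = eps * beta, P_s = 1 - alpha (single lineage)
  p2 <- bd_params(0.1, 0.5)
  tr <- bd_transients(10, p2)
  expect_equal(tr$alpha, 0.5 * tr$beta)
  expect_equal(tr$p_survival, 1 - tr$alpha, tolerance = 1e-12)
  expect_error(bd_transients(-1, p), "t must be")
  # numerically stable far into the saturated regime
  big <- bd_transients(7000, p2)
  expect_equal(big$beta, 1)
  expect_equal(big$p_survival, 1 - p2$eps)
})

test_that("bd_params validates its domain and implies lambda/mu", {
  p <- bd_params(0.05, 0.6)
  expect_equal(p$lambda - p$mu, 0.05)
  expect_equal(p$mu / p$lambda, 0.6)
  expect_error(bd_params(0, 0), "r must be")
  expect_error(bd_params(0.1, 1), "eps must be")
})

test_that("richness pmf matches closed forms, normalizes, and guards n = 0", {
  p <- bd_params(0.1, 0)
  expect_equal(richness_pmf(1, 10, p, conditioned = TRUE), exp(-1), tolerance = 1e-12)
  expect_error(richness_pmf(0, 10, p, conditioned = TRUE), "outside the support")
  for (eps in c(0, 0.3, 0.9)) {
    for (tt in c(1, 10, 80)) {
      pp <- bd_params(0.07, eps)
      beta <- bd_transients(tt, pp)$beta
      n <- 1:400
      total <- sum(richness_pmf(n, tt, pp, conditioned = TRUE)) + beta^400
      expect_equal(total, 1, tolerance = 1e-10)
      # unconditioned: alpha is the extinction atom
      tr <- bd_transients(tt, pp)
      expect_equal(richness_pmf(0, tt, pp, conditioned = FALSE), tr$alpha, tolerance = 1e-12)
      tot_u <- tr$alpha + sum(richness_pmf(n, tt, pp, conditioned = FALSE)) +
        (1 - tr$alpha) * beta^400
      expect_equal(tot_u, 1, tolerance = 1e-10)
    }
  }
})

test_that("expected richness follows e^{rt} and its survival-conditioned form", {
  p <- bd_params(0.0087352, 0)
  expect_equal(expected_richness(0, p), 1)
  expect_equal(expected_richness(100, p), exp(0.87352), tolerance = 1e-10)
  p2 <- bd_params(0.05, 0.7)
  tt <- c(5, 50, 200)
  expect_equal(expected_richness(tt, p2, conditioned = FALSE), exp(0.05 * tt))
  expect_true(all(expected_richness(tt, p2, conditioned = TRUE) >=
                    expected_richness(tt, p2, conditioned = FALSE)))
})

test_that("richness quantiles are closed-form and monotone", {
  # beta = 0.5 at t = 10 ln 2 with r = 0.1, eps = 0
  p <- bd_params(0.1, 0)
  t_half <- 10 * log(2)
  expect_equal(bd_transients(t_half, p)$beta, 0.5, tolerance = 1e-12)
  expect_equal(richness_quantile(0.75, t_half, p), 2)
  expect_equal(richness_quantile(1e-9, t_half, p), 1)
  qs <- richness_quantile(c(0.1, 0.5, 0.9, 0.99), 40, p)
  expect_true(all(diff(qs) >= 0))
  ts <- richness_quantile(0.9, c(5, 20, 60), p)
  expect_true(all(diff(ts) >= 0))
  # quantile inverts the closed-form CDF: smallest n with 1 - beta^n >= q
  beta <- bd_transients(40, p)$beta
  q <- 0.83
  nq <- richness_quantile(q, 40, p)
  expect_gte(1 - beta^nq, q)
  expect_lt(1 - beta^(nq - 1), q)
})

test_that("internal likelihood reduces to the Yule closed form at eps = 0", {
  # 3-terminal chronogram, splits at 10 and 5 Ma: one internal branch (10 -> 5)
  rt <- toy_rt("((A:5,B:5):5,C:10);")
  br <- data.frame(t1 = 10, t2 = 5)
  r <- 0.1
  expect_equal(internal_loglik(br, bd_params(r, 0)), log(r) - r * 5, tolerance = 1e-12)
  # Yule MLE: r_hat = (N - 2) / S with S the summed internal branch durations
  set.seed(5)
  phy <- ape::rcoal(40)
  phy$edge.length <- phy$edge.length * 30
  ch <- as_chronogram(phy)
  rt2 <- species_rt(ch)
  ib <- rt2$edges[!rt2$edges$is_term, ]
  S <- sum(ib$t1 - ib$t2)
  N <- 40
  opt <- optimize(function(r) -internal_loglik(ib, bd_params(r, 0)),
                  interval = c(1e-6, 5), tol = 1e-10)
  expect_equal(opt$minimum, (N - 2) / S, tolerance = 1e-5)
  expect_equal(internal_loglik(ib[0, ], bd_params(1, 0)), 0)
})

test_that("combined likelihood equals the Nee crown-conditioned oracle", {
  set.seed(21)
  phy <- ape::rcoal(12)
  phy$edge.length <- phy$edge.length * 40
  rt <- species_rt(as_chronogram(phy))
  for (r in c(0.02, 0.1, 0.6)) {
    for (eps in c(0, 0.4, 0.9)) {
      mine <- combined_loglik(rt, list(bd_params(r, eps)))$lnL_total
      expect_equal(mine, nee_loglik(r, eps, phy), tolerance = 1e-8)
    }
  }
})

test_that("likelihood is additive over any regime partition under shared rates", {
  set.seed(31)
  s <- simulate_bd(bd_params(0.08, 0.3), crown_age = 40, seed = 31)
  col <- collapse_to_higher_taxa(s$recon, 10)
  rt <- col$rt
  p <- bd_params(0.05, 0.2)
  whole <- combined_loglik(rt, list(p))$lnL_total
  # partition at an arbitrary internal node, same params in both regimes
  node <- rt$chronogram$n_tip + 2L
  split2 <- combined_loglik(rt, list(p, p), shift_nodes = node)$lnL_total
  expect_equal(split2, whole, tolerance = 1e-10)
  # terminal component of a star-like regime with all n = 1 is -r * sum(t_i)
  rt3 <- toy_rt("((A:10,B:10):5,C:15);")
  bk <- combined_loglik(rt3, list(bd_params(0.1, 0)))
  expect_equal(bk$lnL_terminal, -0.1 * (10 + 10 + 15), tolerance = 1e-12)
})

test_that("model comparisons are invariant to additive likelihood constants", {
  set.seed(41)
  s <- simulate_bd(bd_params(0.06, 0.2), crown_age = 50, seed = 41)
  col <- collapse_to_higher_taxa(s$recon, 12)
  rt <- col$rt
  node <- rt$chronogram$n_tip + 3L
  p0 <- list(bd_params(0.05, 0.1))
  p1 <- list(bd_params(0.05, 0.1), bd_params(0.2, 0.1))
  d <- combined_loglik(rt, p1, node)$lnL_total - combined_loglik(rt, p0)$lnL_total
  # adding any per-observation constant c (terminals + internals) cancels in
  # differences: emulate by shifting both totals by c * n_obs
  n_obs <- nrow(rt$edges)
  d_shifted <- (combined_loglik(rt, p1, node)$lnL_total + 0.37 * n_obs) -
    (combined_loglik(rt, p0)$lnL_total + 0.37 * n_obs)
  expect_equal(d, d_shifted, tolerance = 1e-12)
})

test_that("fit_params recovers rates and flags uninformative regimes", {
  set.seed(51)
  s <- simulate_bd(bd_params(0.05, 0), n_tips = 300, seed = 51)
  col <- collapse_to_higher_taxa(s$recon, s$recon$root_age / 4)
  fit <- fit_params(col$rt)
  expect_lt(abs(fit$params[[1]]$r - 0.05) / 0.05, 0.35)
  expect_equal(fit$breakdown$lnL_total, fit$lnL)
  # fixed-eps fit exposes one free parameter per regime
  fit2 <- fit_params(col$rt, eps_fixed = 0.2)
  expect_equal(fit2$k, 1L)
  expect_lte(fit2$lnL, fit$lnL + 1e-6)
  # a single monotypic terminal regime carries no information
  rt3 <- toy_rt("((A:10,B:10):5,C:15);")
  expect_error(fit_params(rt3, shift_nodes = match("C", rt3$chronogram$phy$tip.label)),
               "insufficient information")
})
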