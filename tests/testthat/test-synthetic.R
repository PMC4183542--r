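test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_bd(bd_params(0.08, 0.3), crown_age = 30, seed = 123)
  b <- simulate_bd(bd_params(0.08, 0.3), crown_age = 30, seed = 123)
  expect_identical(ape::write.tree(a$recon$phy), ape::write.tree(b$recon$phy))
  sh1 <- simulate_with_shift(bd_params(0.03, 0.1), bd_params(0.12, 0.1), 20, 40, seed = 5)
  sh2 <- simulate_with_shift(bd_params(0.03, 0.1), bd_params(0.12, 0.1), 20, 40, seed = 5)
  expect_identical(ape::write.tree(sh1$recon$phy), ape::write.tree(sh2$recon$phy))
  expect_identical(sh1$true_tips, sh2$true_tips)
})

test_that("pure-birth simulations need no pruning", {
  s <- simulate_bd(bd_params(0.1, 0), crown_age = 30, seed = 3)
  expect_equal(length(s$full$tip.label), s$recon$n_tip)
  expect_true(ape::is.ultrametric(s$recon$phy, tol = 1e-8))
})

test_that("survival fraction and mean clade size match the analytics", {
  p <- bd_params(0.1, 0.5)
  reps <- 10000
  cnt <- simulate_bd_counts(p, t = 10, reps = reps, seed = 42)
  ps <- bd_transients(10, p)$p_survival
  se_ps <- sqrt(ps * (1 - ps) / reps)
  expect_lt(abs(mean(cnt > 0) - ps), 3 * se_ps)
  m <- exp(p$r * 10)  # unconditioned stem expectation
  expect_lt(abs(mean(cnt) - m), 3 * sd(cnt) / sqrt(reps))
})

test_that("simulated clade sizes follow the richness pmf (chi-squared GOF)", {
  p <- bd_params(0.08, 0.4)
  tt <- 15
  reps <- 10000
  cnt <- simulate_bd_counts(p, tt, reps = reps, seed = 99)
  surv <- cnt[cnt > 0]
  # bin 1..19 and a single tail bin
  obs <- c(tabulate(pmin(surv, 20), nbins = 20))
  pr <- richness_pmf(1:19, tt, p, conditioned = TRUE)
  pr <- c(pr, 1 - sum(pr))
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("collapse conserves richness and preserves deep structure", {
  s <- simulate_bd(bd_params(0.07, 0.2), crown_age = 60, seed = 8)
  col <- collapse_to_higher_taxa(s$recon, 20)
  expect_equal(col$rt$total_richness, s$recon$n_tip)
  expect_true(all(col$rt$stem_age > 20))
  expect_true(all(col$rt$chronogram$ages[-(seq_len(col$rt$chronogram$n_tip))] > 20 |
                    abs(col$rt$chronogram$ages[-(seq_len(col$rt$chronogram$n_tip))]) < 1e-9))
  # collapse just above the present: every terminal is a single species and
  # the topology is untouched
  eps_age <- min(s$recon$ages[s$recon$ages > 0]) / 2
  col0 <- collapse_to_higher_taxa(s$recon, eps_age)
  expect_true(all(col0$rt$richness == 1))
  expect_equal(col0$rt$chronogram$n_tip, s$recon$n_tip)
  expect_error(collapse_to_higher_taxa(s$recon, 0), "strictly between")
  expect_error(collapse_to_higher_taxa(s$recon, s$recon$root_age + 1), "strictly between")
})

test_that("shifted simulations report a scoreable true clade", {
  sh <- simulate_with_shift(bd_params(0.02, 0.2), bd_params(0.1, 0.2),
                            shift_age = 20, crown_age = 60, seed = 17)
  expect_true(all(sh$true_tips %in% sh$recon$phy$tip.label))
  expect_setequal(clade_tips(sh$recon, sh$true_node), sh$true_tips)
  # shifted clade should not be the whole tree
  expect_lt(length(sh$true_tips), sh$recon$n_tip)
  expect_error(simulate_with_shift(bd_params(0.02, 0), bd_params(0.1, 0), 70, 60),
               "younger than")
})

test_that("a strong upshift inflates the shifted clade relative to its age", {
  set.seed(300)
  szs <- replicate(15, {
    sh <- simulate_with_shift(bd_params(0.02, 0), bd_params(0.1, 0),
                              shift_age = 30, crown_age = 70)
    length(sh$true_tips)
  })
  # unshifted lineage of age 30 under the root regime: E[n] = e^{0.6} ~ 1.8
  expect_gt(mean(szs), 3 * exp(0.02 * 30))
})

test_that("pseudo-posterior samples perturb ages but keep topology and validity", {
  s <- simulate_bd(bd_params(0.06, 0.1), crown_age = 50, seed = 23)
  ch <- s$recon
  ens0 <- pseudo_posterior(ch, 3, jitter_scale = 0, seed = 1)
  for (e in ens0) expect_equal(e$ages, ch$ages, tolerance = 1e-12)
  ens <- pseudo_posterior(ch, 200, jitter_scale = 0.05, seed = 2)
  roots <- vapply(ens, `[[`, 0, "root_age")
  se <- sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - ch$root_age), 3 * se + 0.01 * ch$root_age)
  for (e in ens[1:5]) {
    expect_identical(e$phy$tip.label, ch$phy$tip.label)
    expect_identical(e$phy$edge, ch$phy$edge)
    # every sample is itself a valid chronogram (parent > child everywhere)
    expect_true(all(e$ages[e$phy$edge[, 1]] > e$ages[e$phy$edge[, 2]]))
  }
  # wider jitter -> wider age spread
  ens2 <- pseudo_posterior(ch, 200, jitter_scale = 0.15, seed = 3)
  expect_gt(sd(vapply(ens2, `[[`, 0, "root_age")), sd(roots))
})
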