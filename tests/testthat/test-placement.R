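test_that("likelihood-ratio statistics follow the chi-squared convention", {
  # arithmetic on published-scale log-likelihood pairs
  lt <- lrt(-11299.630, -11504.581, 3)
  expect_equal(lt$chi2, 409.902, tolerance = 1e-9)
  expect_lt(lt$p, 0.001)
  lt2 <- lrt(-11299.630, -11351.037, 1)
  expect_equal(lt2$chi2, 102.814, tolerance = 1e-9)
  expect_equal(lrt(-5, -5, 1)$chi2, 0)
  expect_equal(lrt(-5, -5, 1)$p, 1)
  # clipped at zero rather than negative
  expect_equal(lrt(-6, -5, 2)$chi2, 0)
  # invariant to additive likelihood constants
  expect_equal(lrt(-11299.630 + 77, -11504.581 + 77, 3)$chi2, lt$chi2)
  expect_error(lrt(-1, -2, 0), "df")
})

test_that("single-shift fits free only the two net rates", {
  sh <- simulate_with_shift(bd_params(0.02, 0.2), bd_params(0.1, 0.2),
                            shift_age = 60, crown_age = 100, seed = 9)
  col <- collapse_to_higher_taxa(sh$recon, 20, mark_tips = sh$true_tips)
  rt <- col$rt
  m0 <- fit_homogeneous(rt)
  eps0 <- m0$params[[1]]$eps
  node <- resolve_clade(rt, col$truth$label[col$truth$marked])
  fit <- single_shift_fit(rt, node, eps_fixed = eps0)
  expect_gt(fit$r_clade, fit$r_root)  # engineered upshift
  expect_gt(fit$lnL, m0$lnL - 1e-9)
  expect_error(single_shift_fit(rt, rt$chronogram$n_tip + 1L, eps0), "whole tree")
})

test_that("on homogeneous trees the two root partitions have near-equal rates", {
  set.seed(61)
  hits <- replicate(10, {
    s <- simulate_bd(bd_params(0.05, 0), n_tips = 150, seed = sample.int(1e6, 1))
    col <- collapse_to_higher_taxa(s$recon, s$recon$root_age / 3)
    rt <- col$rt
    m0 <- fit_homogeneous(rt)
    root <- rt$chronogram$n_tip + 1L
    kids <- rt$chronogram$phy$edge[rt$chronogram$phy$edge[, 1] == root, 2]
    kid <- kids[which.max(vapply(kids, function(v) length(clade_tips(rt, v)), 0L))]
    f <- tryCatch(single_shift_fit(rt, kid, m0$params[[1]]$eps), error = function(e) NULL)
    if (is.null(f)) return(NA)
    lrt(f$lnL, m0$lnL, 1)$p > 0.05
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.7)
})

test_that("placement scans rank candidates and tolerate unresolvable ones", {
  sh <- simulate_with_shift(bd_params(0.02, 0.2), bd_params(0.1, 0.2),
                            shift_age = 60, crown_age = 100, seed = 9)
  col <- collapse_to_higher_taxa(sh$recon, 20, mark_tips = sh$true_tips)
  rt <- col$rt
  m0 <- fit_homogeneous(rt)
  true_labs <- col$truth$label[col$truth$marked]
  # wrong candidate: a small cherry nested deep inside the shifted clade (a
  # clearly worse placement that still fits; the complement of the true clade
  # would be an equivalent root partition, not a wrong one)
  phy <- rt$chronogram$phy
  n <- rt$chronogram$n_tip
  cherry <- NULL
  for (v in (n + 2L):(n + phy$Nnode)) {
    tps <- clade_tips(rt, v)
    if (length(tps) == 2 && all(tps %in% true_labs) &&
        length(tps) < length(true_labs)) { cherry <- tps; break }
  }
  cands <- list(true_clade = true_labs,
                wrong_cherry = cherry,
                broken = c("NOPE1", "NOPE2"))
  tab <- placement_scan(rt, cands, eps_fixed = m0$params[[1]]$eps)
  expect_equal(attr(tab, "best"), "true_clade")
  expect_match(tab$status[tab$candidate == "broken"], "error")
  expect_gt(tab$lnL[tab$candidate == "true_clade"], tab$lnL[tab$candidate == "wrong_cherry"])
  expect_equal(tab$rank[tab$candidate == "true_clade"], 1L)
  # LRT columns against the best candidate
  second <- tab$candidate[which(tab$rank == 2L)]
  expect_equal(tab$chi2_vs_best[tab$candidate == second],
               2 * (tab$lnL[1] - tab$lnL[tab$candidate == second]), tolerance = 1e-9)
  lv <- attr(tab, "lrt_vs_uniform")
  expect_equal(lv$chi2, 2 * (tab$lnL[1] - attr(tab, "uniform_lnL")), tolerance = 1e-9)
  # empty candidate list gives an empty table
  empty <- placement_scan(rt, list(), eps_fixed = m0$params[[1]]$eps)
  expect_equal(nrow(empty), 0L)
})

test_that("the best single-shift placement matches the one-shift stepwise model", {
  sh <- simulate_with_shift(bd_params(0.02, 0.2), bd_params(0.1, 0.2),
                            shift_age = 60, crown_age = 100, seed = 9)
  col <- collapse_to_higher_taxa(sh$recon, 20, mark_tips = sh$true_tips)
  rt <- col$rt
  models <- stepwise_search(rt, max_shifts = 1)
  final <- models[[length(models)]]
  first <- final$shift_nodes[1]
  m0 <- models[[1]]
  alt <- setdiff(c(rt$chronogram$n_tip + 2L, rt$chronogram$n_tip + 3L), first)[1]
  cands <- list(best_from_search = clade_tips(rt, first),
                alternative = clade_tips(rt, alt))
  tab <- placement_scan(rt, cands, eps_fixed = m0$params[[1]]$eps)
  expect_equal(attr(tab, "best"), "best_from_search")
})
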