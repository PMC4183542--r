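#' Birth-death regime parameters
#'
#' A diversification regime is parameterized by the net diversification rate
#' r = lambda - mu (per Ma) and the turnover (relative extinction)
#' eps = mu / lambda, from which the speciation rate lambda = r / (1 - eps)
#' and extinction rate mu = lambda * eps are implied.
#'
#' @param r net diversification rate, > 0 (per Ma).
#' @param eps turnover, in [0, 1).
#' @return object of class `bd_params` with fields `r`, `eps`, `lambda`, `mu`.
#' @export
bd_params <- function(r, eps = 0) {
  if (!is.finite(r) || r <= 0) stop("r must be > 0")
  if (!is.finite(eps) || eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  lambda <- r / (1 - eps)
  structure(list(r = r, eps = eps, lambda = lambda, mu = lambda * eps),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("birth-death regime: r = %.6g /Ma, eps = %.4g (lambda = %.6g, mu = %.6g)\n",
              x$r, x$eps, x$lambda, x$mu))
  invisible(x)
}

#' Birth-death transient probabilities at an age
#'
#' For a single lineage observed `t` Ma before the present:
#' beta(t) = (e^{rt} - 1) / (e^{rt} - eps) is the geometric parameter of the
#' clade-size distribution, alpha(t) = eps * beta(t) the extinction mass, and
#' P_s(t) = (1 - eps) / (1 - eps e^{-rt}) the probability of leaving at least
#' one extant descendant. All are evaluated with the exponentials written in
#' e^{-rt} form, which is stable for r t up to (and far beyond) ~700.
#'
#' @param t age(s) in Ma, >= 0.
#' @param params a [bd_params()] regime.
#' @return list with numeric vectors `beta`, `alpha`, `p_survival`.
#' @export
bd_transients <- function(t, params) {
  if (any(t < 0)) stop("age t must be >= 0")
  E <- exp(-params$r * t)
  beta <- (1 - E) / (1 - params$eps * E)
  list(beta = beta, alpha = params$eps * beta,
       p_survival = (1 - params$eps) / (1 - params$eps * E))
}

# log(beta) and log(1 - beta), stable forms
.log_beta <- function(t, r, eps) {
  E <- exp(-r * t)
  log(-expm1(-r * t)) - log1p(-eps * E)
}
.log_1m_beta <- function(t, r, eps) {
  E <- exp(-r * t)
  -r * t + log1p(-eps) - log1p(-eps * E)
}

#' Probability mass of a clade's extant richness
#'
#' Distribution of the number of extant species descending from a single
#' lineage of age `t` under a constant-rate birth-death regime. Unconditioned:
#' P(0) = alpha, P(n) = (1 - alpha)(1 - beta) beta^{n-1} for n >= 1.
#' Conditioned on survival (the form used for observed terminal clades):
#' P(n) = (1 - beta) beta^{n-1}, a geometric distribution.
#'
#' @param n count(s), integer; >= 1 when `conditioned`, >= 0 otherwise.
#' @param t age(s) in Ma, > 0.
#' @param params a [bd_params()] regime.
#' @param conditioned condition on survival to the present.
#' @param log return log-probabilities.
#' @return numeric vector of (log-)probabilities.
#' @export
richness_pmf <- function(n, t, params, conditioned = TRUE, log = FALSE) {
  if (any(t < 0)) stop("age t must be >= 0")
  if (any(n != round(n)) || any(n < 0)) stop("n must be a non-negative integer")
  if (conditioned && any(n == 0)) stop("n = 0 is outside the support of the survival-conditioned distribution")
  k <- pmax(length(n), length(t))
  n <- rep_len(n, k); t <- rep_len(t, k)
  r <- params$r; eps <- params$eps
  lb <- .log_beta(t, r, eps)
  l1mb <- .log_1m_beta(t, r, eps)
  lp <- ifelse(n == 0, NA_real_, l1mb + ifelse(n == 1, 0, (n - 1) * lb))
  if (!conditioned) {
    E <- exp(-r * t)
    tr <- bd_transients(t, params)
    l1ma <- log1p(-eps) - log1p(-eps * E)   # log(1 - alpha)
    lp <- ifelse(n == 0, base::log(tr$alpha), l1ma + lp)
  }
  if (log) lp else exp(lp)
}

#' Expected extant richness of a clade of age t
#'
#' Unconditioned mean e^{rt}; conditioned on survival, e^{rt} / (1 - alpha(t)).
#'
#' @inheritParams richness_pmf
#' @return numeric vector of expected counts.
#' @export
expected_richness <- function(t, params, conditioned = TRUE) {
  if (any(t < 0)) stop("age t must be >= 0")
  m <- exp(params$r * t)
  if (!conditioned) return(m)
  m / (1 - bd_transients(t, params)$alpha)
}

#' Quantile of the survival-conditioned clade-size distribution
#'
#' Smallest n >= 1 with P(N <= n) = 1 - beta^n >= q, in closed form.
#'
#' @param q probability (or vector), in (0, 1).
#' @param t age in Ma.
#' @param params a [bd_params()] regime.
#' @return integer-valued numeric vector of counts.
#' @export
richness_quantile <- function(q, t, params) {
  if (any(q <= 0) || any(q >= 1)) stop("q must be in (0, 1)")
  k <- max(length(q), length(t))
  q <- rep_len(q, k); t <- rep_len(t, k)
  beta <- bd_transients(t, params)$beta
  lb <- .log_beta(t, params$r, params$eps)
  out <- ifelse(beta <= 0, 1, ceiling(log1p(-q) / lb - 1e-9))
  pmax(out, 1)
}

#' Log-likelihood of the internal splits of a regime
#'
#' The reconstructed-process (Nee) likelihood of the observed split times,
#' written as a sum of per-branch terms so that regimes partition cleanly:
#' every internal branch, running from age `t1` (its origin, rootward) down to
#' age `t2` where it ends in an observed split, contributes
#' log lambda + log P_s(t2) + log P(1 -> 1 reconstructed | survival), which
#' collapses to the stable closed form
#' log r - r (t1 - t2) - log(1 - eps e^{-r t1});
#' see the methods vignette for the derivation. With eps = 0 this reduces to
#' the Yule likelihood, maximized at r = (number of branches)/(summed branch
#' durations). The empty regime contributes 0. The root split
#' itself is conditioned upon and contributes no term.
#'
#' @param branches data.frame with columns `t1` (origin age) and `t2`
#'   (split age), one row per internal branch; `t1 > t2 >= 0`.
#' @param params a [bd_params()] regime.
#' @return log-likelihood (scalar).
#' @export
internal_loglik <- function(branches, params) {
  if (is.null(branches) || nrow(branches) == 0) return(0)
  if (any(branches$t1 <= branches$t2)) stop("internal branch with t1 <= t2")
  r <- params$r; eps <- params$eps
  sum(log(r) - r * (branches$t1 - branches$t2) - log1p(-eps * exp(-r * branches$t1)))
}

# --- regime assignment -------------------------------------------------------

#' Assign every branch of a richness tree to a diversification regime
#'
#' Regime 1 is the root (background) regime. Each shift node opens a new
#' regime spanning its clade; with `cut = "stem"` (default) the regime also
#' claims the shift clade's stem branch, with `cut = "node"` it begins at the
#' crown. Nested shifts override outer ones on their own subtree.
#'
#' @param rt a [richness_tree()].
#' @param shift_nodes integer vector of ape node numbers (may be empty).
#' @param cut `"stem"` or `"node"`.
#' @return integer vector, one regime index (1 = root regime, 1 + i for the
#'   i-th shift) per edge row of `rt$edges`.
#' @export
regime_assignment <- function(rt, shift_nodes = integer(0), cut = c("stem", "node")) {
  cut <- match.arg(cut)
  assign <- rep.int(1L, nrow(rt$edges))
  if (!length(shift_nodes)) return(assign)
  sizes <- lengths(rt$edge_desc[shift_nodes])
  ord <- order(sizes, decreasing = TRUE)
  for (i in ord) {
    v <- shift_nodes[i]
    sel <- rt$edge_desc[[v]]
    if (cut == "node") sel <- sel[rt$edges$child[sel] != v]
    assign[sel] <- i + 1L
  }
  assign
}

# split a richness tree's branch data by regime; returns per-regime list of
# plain vectors (internal branch start/end ages; terminal stem ages/counts)
.regime_data <- function(rt, assign, n_regimes) {
  e <- rt$edges
  lapply(seq_len(n_regimes), function(i) {
    sel <- assign == i
    it <- sel & !e$is_term
    tm <- sel & e$is_term
    list(int_t1 = e$t1[it], int_t2 = e$t2[it],
         term_t = e$t1[tm], term_n = e$n[tm])
  })
}

# negative combined log-likelihood of one regime
.regime_negll <- function(r, eps, dat) {
  if (!is.finite(r) || r <= 0 || eps < 0 || eps >= 1) return(1e100)
  v <- 0
  ni <- length(dat$int_t1)
  if (ni) {
    v <- ni * log(r) - r * sum(dat$int_t1 - dat$int_t2) -
      sum(log1p(-eps * exp(-r * dat$int_t1)))
  }
  nt <- length(dat$term_t)
  if (nt) {
    tt <- dat$term_t; nn <- dat$term_n
    E <- exp(-r * tt)
    l1e <- log1p(-eps * E)
    # log(1-beta) and (n-1) log(beta), inlined for speed
    v <- v + sum(-r * tt + log1p(-eps) - l1e) +
      sum((nn - 1) * (log(-expm1(-r * tt)) - l1e))
  }
  if (!is.finite(v)) return(1e100)
  -v
}

.EPS_MAX <- 0.999
.BD_STARTS <- list(c(0.001, 0.05), c(0.005, 0.5), c(0.02, 0.2), c(0.1, 0.8), c(0.5, 0.5))

# TRUE if the regime carries no information to identify r (would run to the
# r -> 0 boundary): no internal splits and every terminal monotypic
.regime_degenerate <- function(dat) {
  length(dat$int_t1) == 0 && (length(dat$term_n) == 0 || all(dat$term_n == 1))
}

# ML fit of one regime; deterministic multi-start over .BD_STARTS plus an
# optional warm start. eps_fixed switches to a 1-D golden-section fit of r.
.fit_regime <- function(dat, eps_fixed = NULL, warm = NULL, starts = .BD_STARTS,
                        rel_tol = 1e-12) {
  if (.regime_degenerate(dat))
    stop("regime has insufficient information (no splits and all terminals monotypic)")
  if (!is.null(eps_fixed)) {
    f <- function(lr) .regime_negll(exp(lr), eps_fixed, dat)
    opt <- stats::optimize(f, interval = c(log(1e-8), log(10)), tol = 1e-12)
    r_hat <- exp(opt$minimum)
    return(list(params = bd_params(r_hat, eps_fixed), lnL = -opt$objective,
                convergence = 0L, free = 1L))
  }
  obj <- function(p) .regime_negll(exp(p[1]), .EPS_MAX * stats::plogis(p[2]), dat)
  st <- starts
  if (!is.null(warm)) st <- c(list(c(warm$r, max(min(warm$eps, 0.99), 1e-6))), st)
  best <- NULL
  for (s in st) {
    p0 <- c(log(s[1]), stats::qlogis(min(s[2], 0.99) / .EPS_MAX))
    fit <- tryCatch(
      stats::nlminb(p0, obj, lower = c(log(1e-8), -30), upper = c(log(10), 12),
                    control = list(rel.tol = rel_tol, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("optimizer failed to converge from every start")
  list(params = bd_params(exp(best$par[1]), .EPS_MAX * stats::plogis(best$par[2])),
       lnL = -best$objective, convergence = best$convergence, free = 2L)
}

#' Combined phylogenetic + taxonomic log-likelihood of a regime partition
#'
#' Sums, over regimes, the internal-splits likelihood ([internal_loglik()])
#' and the survival-conditioned richness pmf of every terminal clade evaluated
#' at its stem age.
#'
#' @param rt a [richness_tree()].
#' @param params_list list of [bd_params()], one per regime (regime 1 = root
#'   regime, then one per shift node in order).
#' @param shift_nodes integer vector of shift nodes (may be empty).
#' @param cut shift placement convention, see [regime_assignment()].
#' @return list with `lnL_internal`, `lnL_terminal`, `lnL_total` and
#'   `per_regime` (data.frame of per-regime components).
#' @export
combined_loglik <- function(rt, params_list, shift_nodes = integer(0), cut = "stem") {
  if (length(params_list) != length(shift_nodes) + 1L)
    stop("need exactly one bd_params per regime (1 + number of shifts); a regime is unassigned")
  assign <- regime_assignment(rt, shift_nodes, cut)
  dats <- .regime_data(rt, assign, length(params_list))
  li <- lt <- numeric(length(dats))
  for (i in seq_along(dats)) {
    p <- params_list[[i]]
    d <- dats[[i]]
    li[i] <- internal_loglik(data.frame(t1 = d$int_t1, t2 = d$int_t2), p)
    lt[i] <- if (length(d$term_t))
      sum(richness_pmf(d$term_n, d$term_t, p, conditioned = TRUE, log = TRUE)) else 0
  }
  list(lnL_internal = sum(li), lnL_terminal = sum(lt), lnL_total = sum(li) + sum(lt),
       per_regime = data.frame(regime = seq_along(dats), lnL_internal = li, lnL_terminal = lt))
}

#' Maximum-likelihood fit of birth-death parameters for a regime partition
#'
#' Each regime is fitted independently (the combined likelihood is additive
#' over the partition): free (r, eps) by bounded quasi-Newton optimization on
#' (log r, logit eps) from a fixed deterministic set of starts, or free r only
#' when `eps_fixed` is supplied.
#'
#' @inheritParams combined_loglik
#' @param eps_fixed optional turnover value shared by all regimes; when given
#'   only r is free per regime.
#' @return list with `params` (list of fitted [bd_params()]), `lnL`,
#'   `breakdown` (as [combined_loglik()]), `k` (number of free rate
#'   parameters) and `convergence`.
#' @export
fit_params <- function(rt, shift_nodes = integer(0), eps_fixed = NULL, cut = "stem") {
  assign <- regime_assignment(rt, shift_nodes, cut)
  dats <- .regime_data(rt, assign, length(shift_nodes) + 1L)
  fits <- lapply(dats, .fit_regime, eps_fixed = eps_fixed)
  params <- lapply(fits, `[[`, "params")
  bk <- combined_loglik(rt, params, shift_nodes, cut)
  list(params = params, lnL = bk$lnL_total, breakdown = bk,
       k = sum(vapply(fits, `[[`, 0L, "free")),
       convergence = vapply(fits, `[[`, 0L, "convergence"))
}
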