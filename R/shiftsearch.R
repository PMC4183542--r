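#' @title MEDUSA-style stepwise shift detection
#' @description Internal constructor for fitted shift models.
#' @noRd
.make_shift_model <- function(rt, shift_nodes, fits, cut, flags = character(0)) {
  params <- lapply(fits, `[[`, "params")
  bk <- combined_loglik(rt, params, shift_nodes, cut)
  lnL <- bk$lnL_total
  k <- 2L + 3L * length(shift_nodes)
  assign <- regime_assignment(rt, shift_nodes, cut)
  n_term <- vapply(seq_along(params), function(i) sum(rt$edges$is_term[assign == i]), 0L)
  structure(list(
    rt = rt, shift_nodes = shift_nodes, cut = cut,
    params = params,
    regimes = data.frame(
      regime = seq_along(params),
      shift_node = c(NA_integer_, shift_nodes),
      r = vapply(params, `[[`, 0, "r"),
      eps = vapply(params, `[[`, 0, "eps"),
      n_edges = as.integer(table(factor(assign, levels = seq_along(params)))),
      n_terminals = n_term),
    assignment = assign,
    regime_lnL = bk$per_regime$lnL_internal + bk$per_regime$lnL_terminal,
    lnL = lnL, breakdown = bk, k = k, AIC = 2 * k - 2 * lnL,
    flags = flags),
    class = "shift_model")
}

#' Fit the homogeneous (no-shift) diversification model
#'
#' A single birth-death regime with free (r, eps) over the whole tree; k = 2.
#'
#' @param rt a [richness_tree()].
#' @param cut shift placement convention carried into downstream search.
#' @return a `shift_model` with zero shifts.
#' @export
fit_homogeneous <- function(rt, cut = "stem") {
  fit <- fit_params(rt)
  flags <- if (rt$chronogram$n_tip < 3) "low_information" else character(0)
  m <- .make_shift_model(rt, integer(0), list(list(params = fit$params[[1]])), cut, flags)
  m
}

#' Evaluate a candidate diversification shift
#'
#' Adds a new regime at `node` (cut at the clade's stem by default) to the
#' current model and re-optimizes the affected regimes: the new regime and the
#' donor regime it was carved from are refit; untouched regimes keep their
#' parameters (`scan = TRUE`), or every regime is refit from the full start
#' set (`scan = FALSE`, used to polish an accepted shift).
#'
#' @param rt a [richness_tree()].
#' @param model the current `shift_model`.
#' @param node candidate ape node number.
#' @param scan cheap warm-started refit (see Details).
#' @return a candidate `shift_model`, or `NULL` if the candidate is
#'   infeasible (a regime would be left without information).
#' @export
try_shift <- function(rt, model, node, scan = TRUE) {
  if (node %in% model$shift_nodes) stop("node is already a shift node")
  root <- rt$chronogram$n_tip + 1L
  shifts <- c(model$shift_nodes, node)
  if (node == root) {
    # degenerate placement: the "new" regime is the whole tree again
    fit <- fit_params(rt)
    fits <- c(list(list(params = fit$params[[1]])), list(list(params = fit$params[[1]])))
    return(.make_shift_model(rt, shifts, fits, model$cut, "degenerate_root_shift"))
  }
  assign <- regime_assignment(rt, shifts, model$cut)
  new_idx <- length(shifts) + 1L
  stem_edge <- which(rt$edges$child == node)
  donor_idx <- model$assignment[stem_edge]
  dats <- .regime_data(rt, assign, new_idx)
  if (.regime_degenerate(dats[[new_idx]]) || .regime_degenerate(dats[[donor_idx]]))
    return(NULL)
  fits <- vector("list", new_idx)
  for (i in seq_len(new_idx - 1L)) fits[[i]] <- list(params = model$params[[i]])
  refit <- if (scan) {
    function(dat, warm) .fit_regime(dat, warm = warm, starts = .BD_STARTS[3], rel_tol = 1e-9)
  } else {
    function(dat, warm) .fit_regime(dat, warm = warm)
  }
  res <- tryCatch({
    fits[[new_idx]] <- refit(dats[[new_idx]], model$params[[donor_idx]])
    fits[[donor_idx]] <- refit(dats[[donor_idx]], model$params[[donor_idx]])
    .make_shift_model(rt, shifts, fits, model$cut)
  }, error = function(e) NULL)
  res
}

# cheap candidate evaluation: AIC gain of adding a shift at `node`, using the
# additivity of the combined likelihood over regimes (only the new regime and
# its donor change). Returns NA for infeasible candidates.
.scan_shift_gain <- function(rt, model, node) {
  stem_edge <- rt$stem_edge[node]
  donor_idx <- model$assignment[stem_edge]
  sel <- rt$edge_desc[[node]]
  if (model$cut == "node") sel <- sel[sel != stem_edge]
  move <- sel[model$assignment[sel] == donor_idx]
  donor_keep <- setdiff(which(model$assignment == donor_idx), move)
  e <- rt$edges
  mkdat <- function(ix) {
    it <- ix[!e$is_term[ix]]; tm <- ix[e$is_term[ix]]
    list(int_t1 = e$t1[it], int_t2 = e$t2[it], term_t = e$t1[tm], term_n = e$n[tm])
  }
  dat_new <- mkdat(move); dat_donor <- mkdat(donor_keep)
  if (.regime_degenerate(dat_new) || .regime_degenerate(dat_donor)) return(NA_real_)
  warm <- model$params[[donor_idx]]
  f <- tryCatch({
    fn <- .fit_regime(dat_new, warm = warm, starts = .BD_STARTS[3], rel_tol = 1e-9)
    fd <- .fit_regime(dat_donor, warm = warm, starts = .BD_STARTS[3], rel_tol = 1e-9)
    fn$lnL + fd$lnL
  }, error = function(e) NA_real_)
  if (is.na(f)) return(NA_real_)
  dlnL <- f - model$regime_lnL[donor_idx]
  2 * dlnL - 6  # AIC gain: 2*dlnL - 2*dk, dk = 3 per shift
}

#' Stepwise (greedy forward) search for diversification-rate shifts
#'
#' At each step every non-root node that is not already a shift is evaluated
#' with [try_shift()]; the candidate with the largest AIC improvement is
#' accepted if the improvement reaches `aic_threshold`, the accepted model is
#' re-polished with the full multistart set, and the search continues until
#' no candidate clears the threshold or `max_shifts` is reached. Ties are
#' broken by the smallest canonical node id, so the result does not depend on
#' candidate evaluation order.
#'
#' @param rt a [richness_tree()].
#' @param aic_threshold minimum AIC improvement to accept a shift (default 4).
#' @param max_shifts cap on the number of accepted shifts.
#' @param cut shift placement convention, `"stem"` (default) or `"node"`.
#' @return list of `shift_model`s, from the homogeneous model to the final
#'   accepted model, with attribute `steps`: a data.frame of accepted steps
#'   (node, lnL, AIC, direction).
#' @export
stepwise_search <- function(rt, aic_threshold = 4, max_shifts = Inf, cut = "stem") {
  if (aic_threshold <= 0) stop("aic_threshold must be > 0")
  canon <- rt$chronogram$canon
  root <- rt$chronogram$n_tip + 1L
  models <- list(fit_homogeneous(rt, cut = cut))
  current <- models[[1]]
  repeat {
    if (length(current$shift_nodes) >= max_shifts) break
    cand_nodes <- setdiff(seq_along(canon), c(root, current$shift_nodes))
    gains <- vapply(cand_nodes, function(v) .scan_shift_gain(rt, current, v), 0)
    if (all(is.na(gains))) break
    best_gain <- max(gains, na.rm = TRUE)
    tied <- cand_nodes[!is.na(gains) & gains >= best_gain - 1e-9]
    best_node <- tied[which.min(canon[tied])]
    if (best_gain < aic_threshold) break
    best <- try_shift(rt, current, best_node, scan = FALSE)
    if (is.null(best) || current$AIC - best$AIC < aic_threshold) break
    current <- best
    models[[length(models) + 1L]] <- current
  }
  final <- models[[length(models)]]
  steps <- if (length(final$shift_nodes)) {
    data.frame(step = seq_along(final$shift_nodes),
               node = final$shift_nodes,
               lnL = vapply(models[-1], `[[`, 0, "lnL"),
               AIC = vapply(models[-1], `[[`, 0, "AIC"),
               direction = vapply(final$shift_nodes, function(v)
                 classify_direction(final, v), ""))
  } else {
    data.frame(step = integer(0), node = integer(0), lnL = numeric(0),
               AIC = numeric(0), direction = character(0))
  }
  attr(models, "steps") <- steps
  models
}

#' Classify a shift as a net upshift or downshift
#'
#' A shift is an upshift when the clade's observed richness (corrected for
#' nested shifts) exceeds its expectation under the parental regime at the
#' clade's stem age, i.e. when its richness ratio exceeds 1.
#'
#' @param model a `shift_model`.
#' @param node a shift node of the model.
#' @return `"up"` or `"down"`.
#' @export
classify_direction <- function(model, node) {
  rr <- richness_ratio(model, node)
  if (rr$ratio > 1) "up" else "down"
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("shift model: %d shift(s), lnL = %.3f, k = %d, AIC = %.3f\n",
              length(x$shift_nodes), x$lnL, x$k, x$AIC))
  print(x$regimes, row.names = FALSE)
  invisible(x)
}

#' Structured report of a fitted shift model
#'
#' @param model a `shift_model`.
#' @return a list (JSON-ready) with per-regime parameters, shift leafsets,
#'   likelihood components and AIC.
#' @export
shift_model_report <- function(model) {
  rt <- model$rt
  shift_leafsets <- lapply(model$shift_nodes, function(v) clade_tips(rt, v))
  list(
    n_shifts = length(model$shift_nodes),
    lnL = model$lnL,
    lnL_internal = model$breakdown$lnL_internal,
    lnL_terminal = model$breakdown$lnL_terminal,
    k = model$k,
    AIC = model$AIC,
    cut = model$cut,
    regimes = lapply(seq_along(model$params), function(i) list(
      regime = i,
      shift_node = if (i == 1L) NULL else model$shift_nodes[i - 1L],
      leafset = if (i == 1L) NULL else shift_leafsets[[i - 1L]],
      r = model$params[[i]]$r,
      eps = model$params[[i]]$eps,
      direction = if (i == 1L) NULL else classify_direction(model, model$shift_nodes[i - 1L])))
  )
}

#' Write a shift-model report as JSON
#' @param model a `shift_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shift_model_json <- function(model, path) {
  jsonlite::write_json(shift_model_report(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
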