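#' Observed clade richness corrected for nested shifts
#'
#' The richness a shift clade contributes under its own regime: the summed
#' species counts of the terminals assigned to the focal regime itself, plus
#' one lineage for each immediately nested shift (each nested radiation counts
#' as a single lineage at its origin).
#'
#' @param model a `shift_model`.
#' @param node a shift node of the model.
#' @return integer corrected richness (>= 1).
#' @export
corrected_richness <- function(model, node) {
  i <- .regime_of_shift(model, node)
  rt <- model$rt
  own <- sum(rt$edges$n[model$assignment == i & rt$edges$is_term])
  nested <- sum(vapply(model$shift_nodes, function(w) {
    w != node && .parent_regime(model, w) == i
  }, TRUE))
  own + nested
}

.regime_of_shift <- function(model, node) {
  i <- match(node, model$shift_nodes)
  if (is.na(i)) stop("node ", node, " is not a shift clade of this model")
  i + 1L
}

# regime index of the branch immediately above a shift clade's stem
.parent_regime <- function(model, node) {
  rt <- model$rt
  root <- rt$chronogram$n_tip + 1L
  parent <- rt$edges$parent[rt$edges$child == node]
  if (parent == root) {
    pe <- integer(0)
  } else {
    pe <- which(rt$edges$child == parent)
  }
  if (!length(pe)) 1L else model$assignment[pe]
}

#' Observed / expected richness ratio of a shift clade
#'
#' The clade's corrected richness relative to the survival-conditioned
#' expectation for a clade of its stem age under the parental regime, with a
#' 95% interval obtained by transforming the 2.5% and 97.5% quantiles of the
#' clade-size distribution (observed / upper, observed / lower).
#'
#' @param model a `shift_model`.
#' @param node a shift node of the model.
#' @param parent_params override the parental regime's [bd_params()].
#' @param level CI level on the clade-size distribution (default 0.95).
#' @return list (class `richness_ratio`) with `node`, `age` (stem age, Ma),
#'   `observed`, `expected`, `ci_low_n`, `ci_high_n`, `ratio`, `ratio_low`,
#'   `ratio_high`.
#' @export
richness_ratio <- function(model, node, parent_params = NULL, level = 0.95) {
  rt <- model$rt
  if (is.null(parent_params)) {
    parent_params <- model$params[[.parent_regime(model, node)]]
  }
  age <- rt$edges$t1[rt$edges$child == node]
  if (length(age) != 1 || age <= 0) stop("shift clade must have a positive stem age")
  obs <- corrected_richness(model, node)
  expd <- expected_richness(age, parent_params, conditioned = TRUE)
  a <- (1 - level) / 2
  qs <- richness_quantile(c(a, 1 - a), age, parent_params)
  structure(list(node = node, age = age, observed = obs, expected = expd,
                 ci_low_n = qs[1], ci_high_n = qs[2],
                 ratio = obs / expd,
                 ratio_low = obs / qs[2], ratio_high = obs / qs[1]),
            class = "richness_ratio")
}

#' @export
print.richness_ratio <- function(x, ...) {
  cat(sprintf("richness ratio at node %d (stem age %.4g Ma): %d obs / %.4g exp = %.4g [%.3g, %.3g]\n",
              x$node, x$age, x$observed, x$expected, x$ratio, x$ratio_low, x$ratio_high))
  invisible(x)
}

#' Richness-ratio timeline across all shifts of a model
#'
#' One row per accepted shift, sorted by stem age (oldest first), suitable
#' for plotting richness change against time.
#'
#' @param model a `shift_model` with at least one shift.
#' @return data.frame with columns `node`, `age`, `observed`, `expected`,
#'   `ci_low_n`, `ci_high_n`, `ratio`, `ratio_low`, `ratio_high`,
#'   `direction`.
#' @export
ratio_timeline <- function(model) {
  if (!length(model$shift_nodes)) stop("model has no shifts")
  rows <- lapply(model$shift_nodes, function(v) {
    rr <- richness_ratio(model, v)
    data.frame(node = v, age = rr$age, observed = rr$observed,
               expected = rr$expected, ci_low_n = rr$ci_low_n,
               ci_high_n = rr$ci_high_n, ratio = rr$ratio,
               ratio_low = rr$ratio_low, ratio_high = rr$ratio_high,
               direction = if (rr$ratio > 1) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$age), , drop = FALSE]
}
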