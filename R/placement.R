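#' Single-shift model at a named node with fixed turnover
#'
#' The comparison used to rank alternative placements of the first
#' diversification shift: the tree is split into a root-side and a clade-side
#' regime at `node` (cut at the clade's stem), turnover eps is fixed for both
#' regimes (conventionally at the homogeneous-model estimate), and the net
#' rate r of each regime is fitted freely.
#'
#' @param rt a [richness_tree()].
#' @param node ape node number of the focal clade (must be a proper clade,
#'   not the root).
#' @param eps_fixed turnover value shared by both regimes.
#' @return list with `node`, `lnL`, `r_root`, `r_clade`, `eps`.
#' @export
single_shift_fit <- function(rt, node, eps_fixed) {
  root <- rt$chronogram$n_tip + 1L
  if (node == root) stop("focal clade is the whole tree; no root partition remains")
  fit <- fit_params(rt, shift_nodes = node, eps_fixed = eps_fixed)
  list(node = node, lnL = fit$lnL,
       r_root = fit$params[[1]]$r, r_clade = fit$params[[2]]$r,
       eps = eps_fixed)
}

#' Likelihood-ratio test between two nested diversification models
#'
#' @param lnL_better,lnL_worse log-likelihoods of the better and worse model.
#' @param df degrees of freedom of the comparison (caller-supplied).
#' @return list with `chi2` (= 2 * max(0, lnL_better - lnL_worse)) and `p`
#'   (upper chi-squared tail).
#' @export
lrt <- function(lnL_better, lnL_worse, df) {
  if (df < 1) stop("df must be >= 1")
  chi2 <- 2 * (lnL_better - lnL_worse)
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Scan alternative single-shift placements
#'
#' Fits a single-shift model ([single_shift_fit()]) at every named candidate
#' clade and ranks them by log-likelihood. Likelihood-ratio statistics are
#' reported against the best candidate (default df 1 between alternative
#' placements) and, for the best candidate, against the homogeneous model
#' (default df 3). Unresolvable candidates are kept in the table with an
#' error status and the scan continues.
#'
#' @param rt a [richness_tree()].
#' @param candidates named list; each element a character vector of tip
#'   labels whose MRCA defines the candidate clade.
#' @param eps_fixed turnover fixed for all fits (conventionally the
#'   homogeneous-model estimate; see [fit_homogeneous()]).
#' @param df_between df for comparisons between alternative placements.
#' @param df_vs_uniform df for the best-model vs homogeneous comparison.
#' @return data.frame sorted by lnL (best first) with columns `candidate`,
#'   `status`, `node`, `lnL`, `r_root`, `r_clade`, `chi2_vs_best`, `df`, `p`,
#'   `rank`; attributes `uniform_lnL`, `best`, `second_best`, and
#'   `lrt_vs_uniform` (the best-vs-uniform test).
#' @export
placement_scan <- function(rt, candidates, eps_fixed,
                           df_between = 1, df_vs_uniform = 3) {
  uni <- fit_params(rt, eps_fixed = eps_fixed)
  rows <- lapply(names(candidates), function(nm) {
    res <- tryCatch({
      node <- resolve_clade(rt, candidates[[nm]])
      fit <- single_shift_fit(rt, node, eps_fixed)
      data.frame(candidate = nm, status = "ok", node = node, lnL = fit$lnL,
                 r_root = fit$r_root, r_clade = fit$r_clade,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(candidate = nm, status = paste("error:", conditionMessage(e)),
                 node = NA_integer_, lnL = NA_real_, r_root = NA_real_,
                 r_clade = NA_real_, stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- data.frame(candidate = character(0), status = character(0),
                      node = integer(0), lnL = numeric(0), r_root = numeric(0),
                      r_clade = numeric(0), chi2_vs_best = numeric(0),
                      df = numeric(0), p = numeric(0), rank = integer(0))
    attr(tab, "uniform_lnL") <- uni$lnL
    return(tab)
  }
  tab <- tab[order(-tab$lnL, tab$candidate, na.last = TRUE), , drop = FALSE]
  tab$rank <- ifelse(is.na(tab$lnL), NA_integer_, seq_len(nrow(tab)))
  ok <- which(!is.na(tab$lnL))
  tab$chi2_vs_best <- NA_real_; tab$df <- NA_real_; tab$p <- NA_real_
  if (length(ok)) {
    best_lnL <- tab$lnL[ok[1]]
    for (i in ok[-1]) {
      lt <- lrt(best_lnL, tab$lnL[i], df_between)
      tab$chi2_vs_best[i] <- lt$chi2; tab$df[i] <- df_between; tab$p[i] <- lt$p
    }
    attr(tab, "best") <- tab$candidate[ok[1]]
    attr(tab, "second_best") <- if (length(ok) > 1) tab$candidate[ok[2]] else NA_character_
    attr(tab, "lrt_vs_uniform") <- c(lrt(best_lnL, uni$lnL, df_vs_uniform),
                                     df = df_vs_uniform)
  }
  attr(tab, "uniform_lnL") <- uni$lnL
  rownames(tab) <- NULL
  tab
}
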