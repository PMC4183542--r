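#' Lineage-through-time curve of a clade
#'
#' Reconstructed lineage counts of an MRCA-defined clade as a step function of
#' age: the count is 2 at the clade's crown age and increases by 1 at every
#' binary split, reaching the clade's terminal count at the present.
#'
#' @param chrono a `chronogram` (or `richness_tree`).
#' @param tips optional character vector of tip labels; must induce exactly an
#'   MRCA-defined clade. Default: the whole tree.
#' @return data.frame (class `ltt_curve`) with columns `age` (Ma, decreasing,
#'   starting at the crown age) and `n` (lineages immediately after the split
#'   at that age); attribute `present_count`.
#' @export
ltt_curve <- function(chrono, tips = NULL) {
  ch <- if (inherits(chrono, "richness_tree")) chrono$chronogram else chrono
  stopifnot(inherits(ch, "chronogram"))
  if (is.null(tips)) {
    node <- ch$n_tip + 1L
    tips <- ch$phy$tip.label
  } else {
    node <- resolve_clade(ch, tips)
    have <- clade_tips(ch, node)
    if (!setequal(have, tips))
      stop("tip set does not form a clade; MRCA additionally contains: ",
           paste(utils::head(setdiff(have, tips), 5), collapse = ", "))
  }
  if (node <= ch$n_tip) stop("clade must contain at least two tips")
  members <- .clade_members(ch$phy, node)
  internals <- members[members > ch$n_tip]
  split_ages <- sort(ch$ages[internals], decreasing = TRUE)
  out <- data.frame(age = split_ages, n = seq_along(split_ages) + 1L)
  attr(out, "present_count") <- length(tips)
  class(out) <- c("ltt_curve", class(out))
  out
}

#' Reconstructed lineage count of a clade at given ages
#' @param chrono a `chronogram`.
#' @param tips tip labels of the clade (see [ltt_curve()]); `NULL` = whole tree.
#' @param at ages (Ma) at which to count.
#' @return integer vector: 1 + number of clade splits at or older than each
#'   age, so the count is 2 exactly at the crown age and 1 above it.
#' @export
lineages_at <- function(chrono, tips = NULL, at) {
  cv <- ltt_curve(chrono, tips)
  vapply(at, function(a) 1L + sum(cv$age >= a), 0L)
}

#' Ensemble envelope of lineage-through-time curves
#'
#' Evaluates the clade's lineage count on a fixed age grid for every tree of
#' a fixed-topology ensemble and returns per-age quantiles.
#'
#' @param trees list of `chronogram`s sharing a topology.
#' @param tips tip labels of the clade; `NULL` = whole tree.
#' @param grid_n number of evenly spaced grid ages from the reference crown
#'   age to 0 (default 200). The reference crown age is taken from the first
#'   tree.
#' @param probs quantile probabilities (default 2.5%, 50%, 97.5%).
#' @return data.frame with `age` and one column per quantile (`q2.5`, `q50`,
#'   `q97.5` for the defaults).
#' @export
ltt_envelope <- function(trees, tips = NULL, grid_n = 200,
                         probs = c(0.025, 0.5, 0.975)) {
  if (!length(trees)) stop("empty ensemble")
  crown <- if (is.null(tips)) trees[[1]]$root_age else {
    node <- resolve_clade(trees[[1]], tips)
    trees[[1]]$ages[node]
  }
  grid <- seq(crown, 0, length.out = grid_n)
  counts <- vapply(trees, function(ch) lineages_at(ch, tips, grid),
                   integer(grid_n))
  qs <- t(apply(counts, 1, stats::quantile, probs = probs, type = 1))
  out <- data.frame(age = grid, qs, check.names = FALSE)
  names(out) <- c("age", paste0("q", probs * 100))
  out
}
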