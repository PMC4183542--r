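#' Run the stepwise shift search across an ensemble of dated trees
#'
#' All trees must share the terminal label set and topology (node ages may
#' differ, as in samples from a Bayesian dating posterior). The search runs
#' independently per tree with identical configuration; recovered shifts are
#' recorded as clade leafset keys, which are well defined across the ensemble
#' because the topology is fixed.
#'
#' @param trees list of `chronogram`s sharing one topology.
#' @param richness data.frame as from [read_richness()].
#' @param aic_threshold,max_shifts,cut forwarded to [stepwise_search()].
#' @param progress print a line per tree.
#' @return list with `per_tree` (list of character vectors of clade keys) and
#'   `n_trees`.
#' @export
search_ensemble <- function(trees, richness, aic_threshold = 4, max_shifts = Inf,
                            cut = "stem", progress = FALSE) {
  if (!length(trees)) stop("ensemble must contain at least one tree")
  ref_keys <- .topology_keys(trees[[1]])
  for (i in seq_along(trees)[-1]) {
    ki <- .topology_keys(trees[[i]])
    if (!setequal(ki, ref_keys)) {
      bad <- c(setdiff(ki, ref_keys), setdiff(ref_keys, ki))[1]
      stop("tree ", i, " differs in topology from tree 1; first discordant clade: {",
           bad, "}")
    }
  }
  per_tree <- lapply(seq_along(trees), function(i) {
    rt <- suppressMessages(richness_tree(trees[[i]], richness))
    models <- stepwise_search(rt, aic_threshold = aic_threshold,
                              max_shifts = max_shifts, cut = cut)
    final <- models[[length(models)]]
    keys <- vapply(final$shift_nodes, function(v) clade_key(rt, v), "")
    if (progress) message(sprintf("tree %d/%d: %d shift(s)", i, length(trees), length(keys)))
    keys
  })
  list(per_tree = per_tree, n_trees = length(trees))
}

.topology_keys <- function(ch) {
  n <- ch$n_tip
  vapply((n + 1L):(n + ch$phy$Nnode), function(v) clade_key(ch, v), "")
}

#' Tally shift recovery across an ensemble
#'
#' Counts, for every clade that is a shift in the reference model or in any
#' ensemble tree, the fraction of ensemble trees whose search recovered a
#' shift at exactly that clade (matched by leafset), and assigns the
#' robustness bin: `">80%"`, `">50%"`, `">30%"` or `"<30%"`.
#'
#' @param per_tree list of character vectors of clade keys (from
#'   [search_ensemble()]), one per ensemble tree.
#' @param reference_keys clade keys of the reference (e.g. mean-tree) shifts;
#'   reference shifts recovered in no tree are still reported, with
#'   fraction 0.
#' @param rt optional reference [richness_tree()]; when given, near-miss
#'   diagnostics (recovery at the parent or a child of a reference clade) are
#'   attached as attribute `near_miss`.
#' @return data.frame (class `ensemble_robustness`) with columns `clade`,
#'   `recovery_count`, `ensemble_size`, `recovery_fraction`,
#'   `robustness_bin`, `in_reference`, sorted by recovery fraction
#'   (descending).
#' @export
tally_robustness <- function(per_tree, reference_keys = character(0), rt = NULL) {
  m <- length(per_tree)
  all_keys <- unique(c(reference_keys, unlist(per_tree)))
  counts <- vapply(all_keys, function(k)
    sum(vapply(per_tree, function(s) k %in% s, TRUE)), 0L)
  frac <- counts / m
  out <- data.frame(clade = all_keys, recovery_count = counts,
                    ensemble_size = m, recovery_fraction = frac,
                    robustness_bin = robustness_bin(frac),
                    in_reference = all_keys %in% reference_keys,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$recovery_fraction, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(rt)) {
    attr(out, "near_miss") <- .near_miss(per_tree, reference_keys, rt)
  }
  class(out) <- c("ensemble_robustness", class(out))
  out
}

#' Robustness bin of a recovery fraction
#' @param frac recovery fraction(s) in [0, 1].
#' @return character: `">80%"`, `">50%"`, `">30%"` or `"<30%"`.
#' @export
robustness_bin <- function(frac) {
  ifelse(frac > 0.8, ">80%",
         ifelse(frac > 0.5, ">50%",
                ifelse(frac > 0.3, ">30%", "<30%")))
}

# recovery of the parent or a child clade of each reference clade
.near_miss <- function(per_tree, reference_keys, rt) {
  ch <- rt$chronogram
  phy <- ch$phy
  n <- ch$n_tip
  key_of <- vapply(seq_len(n + phy$Nnode), function(v) clade_key(ch, v), "")
  m <- length(per_tree)
  rows <- lapply(reference_keys, function(k) {
    v <- match(k, key_of)
    if (is.na(v)) return(NULL)
    parent <- phy$edge[phy$edge[, 2] == v, 1]
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    near <- stats::na.omit(key_of[c(parent, kids)])
    cnt <- sum(vapply(per_tree, function(s) any(near %in% s), TRUE))
    data.frame(clade = k, near_miss_count = cnt, near_miss_fraction = cnt / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top-k robustness report
#' @param tal an `ensemble_robustness` table.
#' @param k number of top clades (default 50).
#' @return the first `k` rows.
#' @export
top_shifts <- function(tal, k = 50) utils::head(tal, k)
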