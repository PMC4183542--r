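#' Simulate extant-count replicates of a birth-death process
#'
#' Count-only Gillespie simulation of a single stem lineage of age `t`:
#' exponential waiting times at total rate n (lambda + mu), speciation with
#' probability lambda / (lambda + mu). Used as the Monte-Carlo oracle for
#' [bd_transients()] (survival fraction) and [richness_pmf()] /
#' [expected_richness()] (clade-size distribution).
#'
#' @param params a [bd_params()] regime.
#' @param t stem age in Ma.
#' @param reps number of replicates.
#' @param seed optional integer seed.
#' @param cap abort a replicate that exceeds this many coexisting lineages.
#' @return integer vector of extant counts (0 = clade went extinct).
#' @export
simulate_bd_counts <- function(params, t, reps, seed = NULL, cap = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- params$lambda; mu <- params$mu
  rate <- lambda + mu
  p_spec <- lambda / rate
  out <- integer(reps)
  for (i in seq_len(reps)) {
    n <- 1L; u <- 0
    repeat {
      u <- u + stats::rexp(1L, n * rate)
      if (u >= t) break
      n <- n + (if (stats::runif(1L) < p_spec) 1L else -1L)
      if (n == 0L) break
      if (n > cap) stop("lineage count exceeded cap; lower t or r")
    }
    out[i] <- n
  }
  out
}

# forward-time lineage arrays: each lineage has a parent, a start and end time
# (forward, 0 = origin), and a fate: "split", "extinct", "alive", "open"
# ("open" = truncated at u_stop, used by the two-phase shifted simulation)
.sim_fragment <- function(lambda, mu, u_start, u_stop, max_lineages = 2e5) {
  rate <- lambda + mu
  cap <- 64L
  par <- integer(cap); u0 <- numeric(cap); u1 <- numeric(cap); fate <- character(cap)
  n <- 0L
  grow <- function() {
    cap <<- cap * 2L
    length(par) <<- cap; length(u0) <<- cap; length(u1) <<- cap; length(fate) <<- cap
  }
  new_lineage <- function(p, u) {
    if (n == cap) grow()
    n <<- n + 1L
    par[n] <<- p; u0[n] <<- u; u1[n] <<- NA_real_; fate[n] <<- ""
    n
  }
  stack <- integer(64L); sp <- 1L
  stack[1L] <- new_lineage(0L, u_start)
  while (sp > 0L) {
    i <- stack[sp]; sp <- sp - 1L
    u <- u0[i]
    w <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (u + w >= u_stop) {
      u1[i] <- u_stop; fate[i] <- "alive"
    } else if (mu > 0 && stats::runif(1L) >= lambda / rate) {
      u1[i] <- u + w; fate[i] <- "extinct"
    } else {
      u1[i] <- u + w; fate[i] <- "split"
      a <- new_lineage(i, u + w); b <- new_lineage(i, u + w)
      if (sp + 2L > length(stack)) length(stack) <- 2L * length(stack)
      stack[sp + 1L] <- a; stack[sp + 2L] <- b; sp <- sp + 2L
      if (n > max_lineages) stop("simulated tree exceeded ", max_lineages, " lineages")
    }
  }
  list(par = par[seq_len(n)], u0 = u0[seq_len(n)], u1 = u1[seq_len(n)],
       fate = fate[seq_len(n)])
}

# concatenate fragment `sub` under lineage `at` of fragment `frag`
.graft <- function(frag, at, sub) {
  off <- length(frag$par)
  par2 <- ifelse(sub$par == 0L, at, sub$par + off)
  frag$par <- c(frag$par, par2)
  frag$u0 <- c(frag$u0, sub$u0); frag$u1 <- c(frag$u1, sub$u1)
  frag$fate <- c(frag$fate, sub$fate)
  frag
}

# fragment -> phylo, built directly from the lineage arrays (no Newick
# round-trip). Lineages with fate "alive" end at the present, "extinct"
# earlier; both become tips (labels t<i> / x<i> in lineage order). A single
# root lineage that splits is itself the root node (its stem is dropped);
# multiple root lineages are joined at a synthetic root.
.fragment_phylo <- function(fr) {
  nlin <- length(fr$par)
  is_tip <- fr$fate != "split"
  ntip <- sum(is_tip)
  roots <- which(fr$par == 0L)
  single_split_root <- length(roots) == 1L && fr$fate[roots] == "split"

  labels <- rep(NA_character_, nlin)
  alive <- fr$fate == "alive"
  labels[is_tip & alive] <- sprintf("t%d", seq_len(sum(is_tip & alive)))
  labels[is_tip & !alive] <- sprintf("x%d", seq_len(sum(is_tip & !alive)))

  id <- integer(nlin)
  id[is_tip] <- seq_len(ntip)
  internals <- which(!is_tip)
  if (single_split_root) {
    others <- setdiff(internals, roots)
    id[roots] <- ntip + 1L
    id[others] <- ntip + 1L + seq_along(others)
    nnode <- length(internals)
    has_edge <- seq_len(nlin) != roots
    parent_id <- id[pmax(fr$par, 1L)]
  } else {
    id[internals] <- ntip + 1L + seq_along(internals)
    nnode <- length(internals) + 1L
    has_edge <- rep(TRUE, nlin)
    parent_id <- ifelse(fr$par == 0L, ntip + 1L, id[pmax(fr$par, 1L)])
  }
  phy <- structure(list(
    edge = cbind(parent_id[has_edge], id[has_edge]),
    edge.length = (fr$u1 - fr$u0)[has_edge],
    tip.label = labels[order(id[is_tip])][seq_len(ntip)],
    Nnode = nnode), class = "phylo")
  # tip.label must be in tip-id order
  tl <- character(ntip)
  tl[id[is_tip]] <- labels[is_tip]
  phy$tip.label <- tl
  phy <- stats::reorder(phy)
  list(phylo = phy, labels = labels)
}

.prune_extinct <- function(phy) {
  dead <- grep("^x", phy$tip.label, value = TRUE)
  if (!length(dead)) return(phy)
  if (length(dead) >= length(phy$tip.label) - 1L) return(NULL)
  ape::drop.tip(phy, dead)
}

#' Simulate a dated birth-death tree
#'
#' Continuous-time forward simulation with per-lineage exponential waiting
#' times. With a crown-age stop rule the process starts from two crown
#' lineages at `crown_age` and is conditioned on both leaving extant
#' descendants (resimulate-until-success). With a tip-count stop rule a
#' global Gillespie simulation runs until `n_tips` lineages are extant, and
#' the present is set within the interval during which that count persists.
#' Extinct lineages are pruned to give the reconstructed chronogram.
#'
#' @param params a [bd_params()] regime.
#' @param crown_age crown age in Ma (use exactly one of `crown_age`/`n_tips`).
#' @param n_tips target number of extant tips.
#' @param seed optional integer seed.
#' @param max_attempts resimulation budget for the survival conditioning.
#' @return list with `recon` (reconstructed `chronogram`), `full` (the
#'   complete tree with extinct tips, as a `phylo`), and `attempts`.
#' @export
simulate_bd <- function(params, crown_age = NULL, n_tips = NULL, seed = NULL,
                        max_attempts = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(crown_age) == is.null(n_tips))
    stop("supply exactly one of crown_age or n_tips")
  if (!is.null(crown_age)) return(.sim_crown(params, crown_age, max_attempts))
  .sim_ntips(params, n_tips, max_attempts)
}

.sim_crown <- function(params, crown_age, max_attempts) {
  for (att in seq_len(max_attempts)) {
    left <- .sim_fragment(params$lambda, params$mu, 0, crown_age)
    right <- .sim_fragment(params$lambda, params$mu, 0, crown_age)
    ok <- function(f) any(f$fate == "alive")
    if (!ok(left) || !ok(right)) next
    # root as a zero-length join: the two fragments are the two crown clades
    comb <- list(par = c(0L, 0L), u0 = c(0, 0), u1 = c(0, 0), fate = c("seed", "seed"))
    comb <- .graft(comb, 1L, left)
    comb <- .graft(comb, 2L, right)
    # the seed lineages are zero-length stubs whose single child chains up:
    # rewrite: children of seed i attach to root directly
    keep <- comb$fate != "seed"
    idx <- which(keep)
    remap <- integer(length(comb$par)); remap[idx] <- seq_along(idx)
    par2 <- comb$par[keep]
    par2 <- ifelse(par2 %in% c(1L, 2L), 0L, remap[par2])
    fr <- list(par = par2, u0 = comb$u0[keep], u1 = comb$u1[keep], fate = comb$fate[keep])
    nk <- .fragment_phylo(fr)
    full <- nk$phylo
    recon <- .prune_extinct(full)
    if (is.null(recon) || length(recon$tip.label) < 2L) next
    return(list(recon = as_chronogram(recon), full = full, attempts = att))
  }
  stop("no surviving crown tree in ", max_attempts, " attempts (eps or crown age too high)")
}

.sim_ntips <- function(params, n_tips, max_attempts) {
  lambda <- params$lambda; mu <- params$mu
  rate <- lambda + mu
  p_spec <- lambda / rate
  for (att in seq_len(max_attempts)) {
    cap <- 1024L
    par <- integer(cap); u0 <- numeric(cap); u1 <- numeric(cap); fate <- character(cap)
    par[1:2] <- 0L; u0[1:2] <- 0; u1[1:2] <- NA_real_; fate[1:2] <- ""
    nl <- 2L
    alive <- integer(cap); alive[1:2] <- 1:2; na <- 2L
    u <- 0
    ok <- FALSE
    # pre-drawn randomness, refilled in blocks: unit-exponential waits,
    # event-type uniforms, lineage-choice uniforms
    blk <- 4096L
    rw <- stats::rexp(blk); r1 <- stats::runif(blk); r2 <- stats::runif(blk)
    ri <- 0L
    while (na > 1L) {
      if (ri == blk) {
        rw <- stats::rexp(blk); r1 <- stats::runif(blk); r2 <- stats::runif(blk)
        ri <- 0L
      }
      ri <- ri + 1L
      w <- rw[ri] / (na * rate)
      if (na == n_tips) {
        # present falls uniformly inside the waiting interval at size n_tips
        u <- u + w * r1[ri]
        ok <- TRUE
        break
      }
      u <- u + w
      j <- floor(r2[ri] * na) + 1L
      i <- alive[j]
      if (r1[ri] < p_spec) {
        if (nl + 2L > cap) {
          cap <- cap * 2L
          length(par) <- cap; length(u0) <- cap; length(u1) <- cap
          length(fate) <- cap; length(alive) <- cap
        }
        par[nl + 1L] <- i; par[nl + 2L] <- i
        u0[nl + 1L] <- u; u0[nl + 2L] <- u
        fate[nl + 1L] <- ""; fate[nl + 2L] <- ""
        u1[i] <- u; fate[i] <- "split"
        alive[j] <- nl + 1L
        na <- na + 1L
        alive[na] <- nl + 2L
        nl <- nl + 2L
      } else {
        u1[i] <- u; fate[i] <- "extinct"
        alive[j] <- alive[na]
        na <- na - 1L
      }
      if (nl > 2e5) stop("simulated tree exceeded 2e5 lineages")
    }
    if (!ok) next
    live <- alive[seq_len(na)]
    u1[live] <- u; fate[live] <- "alive"
    fr <- list(par = par[seq_len(nl)], u0 = u0[seq_len(nl)], u1 = u1[seq_len(nl)],
               fate = fate[seq_len(nl)])
    nk <- .fragment_phylo(fr)
    full <- nk$phylo
    recon <- .prune_extinct(full)
    if (is.null(recon) || length(recon$tip.label) != n_tips) next
    return(list(recon = as_chronogram(recon), full = full, attempts = att))
  }
  stop("failed to reach ", n_tips, " extant tips in ", max_attempts, " attempts")
}

#' Simulate a chronogram containing one diversification-rate shift
#'
#' Two-phase simulation: the root regime runs from the crown to `shift_age`;
#' one lineage alive at `shift_age` (chosen uniformly) then switches to the
#' shifted regime, all lineages continuing to the present. Conditioned on
#' both crown lineages and the flagged lineage leaving extant descendants.
#'
#' @param params_root,params_shift [bd_params()] for the background and the
#'   shifted regime.
#' @param shift_age age of the rate shift in Ma (< `crown_age`).
#' @param crown_age crown age in Ma.
#' @param seed optional integer seed.
#' @param max_attempts resimulation budget.
#' @return list with `recon` (`chronogram`), `true_tips` (extant tip labels
#'   descending from the shifted lineage), `true_node` (their MRCA in
#'   `recon`), and `attempts`.
#' @export
simulate_with_shift <- function(params_root, params_shift, shift_age, crown_age,
                                seed = NULL, max_attempts = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (shift_age >= crown_age) stop("shift_age must be younger than crown_age")
  u_shift <- crown_age - shift_age
  for (att in seq_len(max_attempts)) {
    # phase A: two crown fragments truncated at the shift time
    left <- .sim_fragment(params_root$lambda, params_root$mu, 0, u_shift)
    right <- .sim_fragment(params_root$lambda, params_root$mu, 0, u_shift)
    comb <- list(par = c(0L, 0L), u0 = c(0, 0), u1 = c(0, 0), fate = c("seed", "seed"))
    comb <- .graft(comb, 1L, left)
    comb <- .graft(comb, 2L, right)
    crossing <- which(comb$fate == "alive")
    if (length(crossing) < 2L) next
    flagged <- crossing[sample.int(length(crossing), 1L)]
    # phase B: continue every crossing lineage to the present
    flag_children <- integer(0)
    for (i in crossing) {
      p <- if (i == flagged) params_shift else params_root
      sub <- .sim_fragment(p$lambda, p$mu, u_shift, crown_age)
      n_before <- length(comb$par)
      comb$u1[i] <- u_shift; comb$fate[i] <- "cross"
      comb <- .graft(comb, i, sub)
      if (i == flagged) flag_children <- n_before + seq_along(sub$par)
    }
    # splice out the zero-length seed stubs and the unary "cross" joints
    comb$par <- as.integer(comb$par)
    flagged_set <- rep(FALSE, length(comb$par))
    flagged_set[flag_children] <- TRUE
    # propagate: mark descendants of flagged phase-B lineages (already all in
    # flag_children since the grafted fragment is complete)
    drop <- comb$fate %in% c("seed", "cross")
    idx <- which(!drop)
    remap <- integer(length(comb$par)); remap[idx] <- seq_along(idx)
    parent_resolve <- function(p) {
      while (p != 0L && drop[p]) p <- comb$par[p]
      p
    }
    par2 <- vapply(comb$par[idx], parent_resolve, 0L)
    # unary joints: a "cross" lineage has exactly one child fragment root, so
    # its child's u0 stays u_shift but the branch must start at the cross
    # lineage's own u0; extend child start times accordingly
    u0_2 <- comb$u0[idx]
    for (j in seq_along(idx)) {
      i <- idx[j]
      p <- comb$par[i]
      if (p != 0L && drop[p] && comb$fate[p] == "cross") u0_2[j] <- comb$u0[p]
    }
    # (index with pmax: subscript 0 would silently drop elements)
    par2 <- ifelse(par2 == 0L, 0L, remap[pmax(par2, 1L)])
    fr <- list(par = par2, u0 = u0_2, u1 = comb$u1[idx], fate = comb$fate[idx])
    fl <- flagged_set[idx]
    nk <- .fragment_phylo(fr)
    full <- nk$phylo
    true_tips <- nk$labels[fl & fr$fate == "alive"]
    true_tips <- true_tips[!is.na(true_tips)]
    if (length(true_tips) < 1L) next
    recon <- .prune_extinct(full)
    if (is.null(recon) || length(recon$tip.label) < 3L) next
    keep_true <- intersect(true_tips, recon$tip.label)
    if (length(keep_true) < 1L) next
    ch <- as_chronogram(recon)
    node <- resolve_clade(ch, keep_true)
    return(list(recon = ch, true_tips = keep_true, true_node = node, attempts = att))
  }
  stop("no usable shifted tree in ", max_attempts, " attempts")
}

#' Collapse a species-level chronogram into higher-taxon terminals
#'
#' Terminals of the collapsed tree are the lineages crossing `collapse_age`;
#' each carries the extant richness of its descendants. Structure older than
#' `collapse_age` is retained unchanged; the terminal's subtending branch runs
#' from its stem age (> `collapse_age`) to the present. Terminal labels are
#' assigned deterministically (`T0001`, ...) with a sidecar truth table.
#'
#' @param chrono a species-level `chronogram` (reconstructed, ultrametric).
#' @param collapse_age collapse threshold in Ma, 0 < collapse_age < crown age.
#' @param mark_tips optional character vector of species tip labels (e.g. the
#'   true shifted clade); collapsed terminals whose species all fall in this
#'   set are marked in the truth table.
#' @return list with `rt` (a [richness_tree()]), `truth` (data.frame: `label`,
#'   `richness`, `stem_age`, `marked`).
#' @export
collapse_to_higher_taxa <- function(chrono, collapse_age, mark_tips = NULL) {
  stopifnot(inherits(chrono, "chronogram"))
  if (collapse_age <= 0 || collapse_age >= chrono$root_age)
    stop("collapse_age must lie strictly between 0 and the crown age")
  phy <- chrono$phy
  n <- chrono$n_tip
  ages <- chrono$ages
  crossing <- which(ages[phy$edge[, 1]] > collapse_age & ages[phy$edge[, 2]] <= collapse_age)
  # per-node tip counts, representative tip and marked-tip counts in one
  # postorder pass
  m <- phy$Nnode
  ntips_below <- c(rep(1L, n), integer(m))
  marked_below <- c(if (is.null(mark_tips)) rep(FALSE, n) else
    phy$tip.label %in% mark_tips, rep(0L, m))
  marked_below <- as.integer(marked_below)
  rep_tip <- c(seq_len(n), integer(m))
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
    marked_below[p] <- marked_below[p] + marked_below[ch]
    if (rep_tip[p] == 0L) rep_tip[p] <- rep_tip[ch]
  }
  child <- phy$edge[crossing, 2]
  rich <- ntips_below[child]
  reps <- phy$tip.label[rep_tip[child]]
  marked <- !is.null(mark_tips) & marked_below[child] == ntips_below[child]
  new_phy <- if (length(reps) < length(phy$tip.label))
    ape::drop.tip(phy, setdiff(phy$tip.label, reps)) else phy
  # deterministic relabel in the dropped tree's own tip order
  ord <- match(new_phy$tip.label, reps)
  labels <- sprintf("T%04d", seq_along(reps))
  new_phy$tip.label <- labels[ord]
  ch2 <- as_chronogram(new_phy)
  truth <- data.frame(label = labels, richness = rich,
                      marked = marked, stringsAsFactors = FALSE)
  rt <- suppressMessages(richness_tree(ch2, richness_table(truth$label, truth$richness)))
  truth$stem_age <- rt$stem_age[truth$label]
  list(rt = rt, truth = truth)
}

#' Pseudo-posterior ensemble of node-age perturbations
#'
#' Each sample multiplies every internal node age by an independent lognormal
#' factor exp(sigma Z) (median-unbiased), then restores parent > child order
#' root-down by rescaling any violating child age to its original fraction of
#' its parent's age. Topology and labels are untouched; `jitter_scale = 0`
#' returns exact copies.
#'
#' @param chrono a `chronogram`.
#' @param n_samples ensemble size.
#' @param jitter_scale lognormal sigma (>= 0).
#' @param seed optional integer seed.
#' @return list of `chronogram` objects.
#' @export
pseudo_posterior <- function(chrono, n_samples, jitter_scale, seed = NULL) {
  stopifnot(inherits(chrono, "chronogram"))
  if (jitter_scale < 0) stop("jitter_scale must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- chrono$phy
  n <- chrono$n_tip
  internal <- (n + 1L):(n + phy$Nnode)
  # preorder over edges so parents are fixed before children
  pre <- rev(ape::postorder(phy))
  lapply(seq_len(n_samples), function(s) {
    ages <- chrono$ages
    prop <- ages
    prop[internal] <- ages[internal] * exp(stats::rnorm(length(internal), 0, jitter_scale))
    for (e in pre) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      if (ch <= n) next
      if (prop[ch] >= prop[p]) prop[ch] <- prop[p] * (ages[ch] / ages[p])
    }
    new_phy <- phy
    new_phy$edge.length <- prop[phy$edge[, 1]] - prop[phy$edge[, 2]]
    as_chronogram(new_phy)
  })
}
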