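# shared fixture builders (all fixtures are generated in code)

toy_chronogram <- function(text = "((A:10,B:10):5,C:15);") {
  as_chronogram(ape::read.tree(text = text))
}

toy_rt <- function(text = "((A:10,B:10):5,C:15);", richness = NULL) {
  ch <- toy_chronogram(text)
  if (is.null(richness)) richness <- stats::setNames(rep(1L, ch$n_tip), ch$phy$tip.label)
  suppressMessages(richness_tree(ch, richness_table(names(richness), richness)))
}

# species-level richness tree (every terminal a single species)
species_rt <- function(chrono) {
  n <- chrono$n_tip
  suppressMessages(richness_tree(chrono, richness_table(chrono$phy$tip.label, rep(1L, n))))
}

# Nee et al. crown-conditioned birth-death log-likelihood of a complete
# species-level ultrametric tree (independent closed-form oracle; the additive
# log-factorial labelling constant is omitted)
nee_loglik <- function(r, eps, phy) {
  x <- sort(ape::branching.times(phy), decreasing = TRUE)
  N <- length(phy$tip.label)
  x <- c(NA, x)
  (N - 2) * log(r) + r * sum(x[3:N]) + N * log(1 - eps) -
    2 * sum(log(exp(r * x[2:N]) - eps))
}

.ancestors_of <- function(phy, v) {
  root <- length(phy$tip.label) + 1L
  out <- integer(0)
  while (v != root) {
    v <- phy$edge[phy$edge[, 2] == v, 1]
    out <- c(out, v)
  }
  out
}

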