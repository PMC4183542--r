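#!/usr/bin/env Rscript
# Fit the homogeneous (no-shift) birth-death model to the study system:
# the uniform model every shift model is judged against.

suppressMessages(library(cladeshift))
if (!file.exists("results/data/study_tree.nwk"))
  stop("run analysis/01_simulate_study_system.R first")
ch <- read_chronogram("results/data/study_tree.nwk")
rt <- richness_tree(ch, read_richness("results/data/study_richness.tsv"))

m0 <- fit_homogeneous(rt)
print(m0)

out <- list(lnL = m0$lnL, AIC = m0$AIC, k = m0$k,
            r = m0$params[[1]]$r, eps = m0$params[[1]]$eps,
            lnL_internal = m0$breakdown$lnL_internal,
            lnL_terminal = m0$breakdown$lnL_terminal)
jsonlite::write_json(out, "results/uniform_fit.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat(sprintf("uniform model: r = %.5f /Ma, eps = %.3f, lnL = %.3f\n",
            out$r, out$eps, out$lnL))
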