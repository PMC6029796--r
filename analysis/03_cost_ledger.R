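#!/usr/bin/env Rscript
# Step 3 — the deterministic net-cost ledger.
#
# Evaluates the annual net-cost ledger from the packaged baseline
# parameter configuration alone (no data files needed): program costs A,
# utilisation cost differences B, net cost C = A + B. Negative values are
# savings. Writes results/cost_ledger.txt and results/cost_ledger.csv.

suppressPackageStartupMessages(library(hinhcost))

res <- run_pipeline(pipeline_config("results", stages = "cost", seed = 1))
writeLines(render_cost_ledger(res$breakdown, res$params))
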