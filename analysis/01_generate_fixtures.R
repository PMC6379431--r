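#!/usr/bin/env Rscript
# Generates the synthetic study structures used by the downstream analyses:
# a bent (25 deg) vs straight (17 deg) claudin-like pair, a two-domain pair
# with a known 5 A displacement, a four-helix bundle with known axis, and a
# one-site binding titration with known Kd. Ground truth is recorded in
# sidecar truth.json files.

library(cldngeom)

out <- "results/fixtures"
seed <- 1

for (kind in c("kinked_pair", "domain_pair", "bundle", "binding")) {
  files <- make_fixtures(kind, seed = seed, out_dir = file.path(out, kind))
  cat(kind, ":", paste(basename(unlist(files)), collapse = ", "), "\n")
}
cat("fixtures written under", out, "\n")
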