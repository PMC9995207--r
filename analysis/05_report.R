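#!/usr/bin/env Rscript
# Stage 5: figures.
#
# Renders one cumulative-incidence panel per endpoint (policy vs historical
# mean, likelihood-ratio signal days shaded, transition-period marker) from
# the monitoring stage's inputs.

library(switchsignal)

bundle <- read_claims("results/claims")
cohorts <- build_all_cohorts(bundle, 2016:2019)
comparisons <- monitor_endpoints(bundle, cohorts)

files <- render_panels(comparisons, "results/figures")
cat("Rendered", length(files), "panel files under results/figures/\n")
med <- endpoint_catalog()$name[endpoint_catalog()$group == "medication"]
cat("Medication panels:", paste(intersect(names(comparisons), med),
                                collapse = ", "), "\n")
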