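#!/usr/bin/env Rscript
# Stage 3: biosimilar uptake.
#
# Monthly biosimilar share of all infliximab dispensations (by age group and
# payer acceptance) and the policy cohort's daily switch curve with the
# switch-back rate among switchers.

library(switchsignal)

bundle <- read_claims("results/claims")
policy <- build_cohort(bundle, 2019, role = "policy")

share <- monthly_biosimilar_share(bundle)
readr::write_csv(share, "results/monthly_biosimilar_share.csv")

curve <- biosimilar_switch_curve(bundle, policy)
readr::write_csv(curve, "results/switch_curve.csv")

pre <- share[share$age_group == "adult" & share$coverage == "all" &
               share$month >= as.Date("2018-08-01") &
               share$month <= as.Date("2019-08-01") & !share$missing, ]
post <- share[share$age_group == "adult" & share$coverage == "all" &
                share$month == as.Date("2020-08-01"), ]
cat(sprintf("Adult biosimilar share Aug 2018 - Aug 2019 (pre-policy): %.1f-%.1f%%\n",
            min(pre$share), max(pre$share)))
if (nrow(post) == 1 && !post$missing) {
  cat(sprintf("Adult biosimilar share in Aug 2020: %.1f%%\n", post$share))
}
cat(sprintf("Policy-cohort switch uptake by day 365: %.1f%%\n",
            attr(curve, "uptake_pct")))
cat(sprintf("Switch-back to originator among switchers: %.1f%%\n",
            attr(curve, "switch_back_pct")))
cat("Tables written: results/monthly_biosimilar_share.csv, results/switch_curve.csv\n")
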