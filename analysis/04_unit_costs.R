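#!/usr/bin/env Rscript
# Derive each site's unit-cost table from its cost inputs: annuitized
# capital and support staff allocated over active-patient equivalents,
# on-site or centralized laboratory costing, per-provider visit costs,
# and the national drug price list, all restated to 2011 USD.

suppressMessages({library(artcost); library(dplyr)})

prices <- reference_price_table()
site_inputs <- fixture_site_cost_inputs()
unit_costs <- bind_rows(lapply(site_inputs, build_unit_cost_table,
                               pt = prices))
write_unit_cost_table(unit_costs, "results/unit_costs.csv")

cat("Unit costs (2011 USD) derived for", length(site_inputs), "sites\n")
fixed <- unit_costs |> filter(resource_class == "fixed")
cat("Fixed cost per month in care by site:",
    paste(sprintf("%s=%.2f", fixed$site_id, fixed$unit_cost_usd),
          collapse = ", "), "\n")
cd4 <- unit_costs |> filter(code == "cd4")
cat("CD4 cost per test ranges from",
    sprintf("%.2f", min(cd4$unit_cost_usd)), "to",
    sprintf("%.2f", max(cd4$unit_cost_usd)),
    "(centralized vs low-volume on-site laboratories)\n")
cat(sprintf("Annuity factors at 3%%: equipment (5 y) %.4f, buildings (50 y) %.4f\n",
            annuity_factor(0.03, 5), annuity_factor(0.03, 50)))
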