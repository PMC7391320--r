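#!/usr/bin/env Rscript
# Stage 4: alternating-trend cascade classification and prevalence.
#
# A location shows the community-cascade signal when all three groups trend
# significantly with adjacent signs opposed, conditional on a significant
# predator trend (the prerequisite). Prevalence is summarized overall, by
# region, and by exploitation status, and the count of significant predator
# trends is compared with the chance expectation at alpha = .05.

suppressMessages(library(reeftrends))

trends <- readr::read_csv("results/trends.csv", show_col_types = FALSE)
meta <- read_location_table("results/data/locations.csv")
meta$region <- region_from_latitude(meta$latitude)
trends <- dplyr::left_join(trends, dplyr::select(meta, location_id, region),
                           by = "location_id")
trends$constant <- FALSE

cls <- classify_all(trends, method = "ols")
readr::write_csv(cls, "results/cascade.csv", na = "")

prev_all <- summarize_prevalence(cls)
prev_region <- summarize_prevalence(cls, grouping = "region")
prev_status <- summarize_prevalence(cls, meta, grouping = "exploitation_status")
readr::write_csv(dplyr::bind_rows(
  dplyr::mutate(prev_all, group = "all", .before = 1),
  dplyr::rename(prev_region, group = region),
  dplyr::rename(prev_status, group = exploitation_status)
), "results/prevalence.csv", na = "")

n_sig <- prev_all$n_predator_significant
ex <- excess_over_chance(n_sig, nrow(meta), 0.05)
cat(sprintf("%d of %d locations have significant predator trends (~%dx chance; exact %.2f)\n",
            n_sig, nrow(meta), ex$display, ex$ratio))
cat(sprintf("Alternating trends at %d of %d predator-significant locations (%d%%); %d partial\n",
            prev_all$n_alternating, n_sig, prev_all$pct_alternating_display,
            prev_all$n_partial_alternating))
cat("\nBy region:\n")
print(as.data.frame(prev_region))
cat("\nObserved cascade patterns:\n")
print(table(cls$pattern[cls$alternating]))
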