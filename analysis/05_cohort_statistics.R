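#!/usr/bin/env Rscript
# The cohort statistics layer on the simulated tables from
# 01_simulate_cohort.R: quality filtering, group descriptives, stall
# rates, skew/kurtosis, flux-diameter and glucose regressions, age
# grouping, thickness comparison, and grader agreement (Bland-Altman).

library(capillux)

out <- "results"
if (!file.exists(file.path(out, "cohort_mice.csv")))
  stop("run analysis/01_simulate_cohort.R first")
co <- read_cohort(file.path(out, "cohort"))

caps <- filter_by_quality(co$capillaries, 3)
cat(sprintf("quality filter: %d of %d scans retained (%.1f%%)\n",
            nrow(caps), nrow(co$capillaries),
            100 * nrow(caps) / nrow(co$capillaries)))

eu <- caps$group == "euglycemic"
for (g in c(TRUE, FALSE)) {
  f <- caps$flux_cells_s[eu == g]
  cat(sprintf("%s flux: %.2f +/- %.2f cells/s, skew %.2f, kurtosis %.2f, stalls %s\n",
              if (g) "euglycemic" else "hyperglycemic", mean(f), sd(f),
              adjusted_skew(f), excess_kurtosis(f),
              attr(stall_rate(caps$stalled[eu == g]), "display")))
}
cmp <- group_compare(caps$flux_cells_s[!eu], caps$flux_cells_s[eu])
cat(sprintf("flux comparison (all observations): p = %.3g\n", cmp$p))
# observations cluster within capillaries; the capillary-level test is
# the fairer read on a finite capillary sample
cap_mean <- aggregate(flux_cells_s ~ mouse_id + capillary_id + group,
                      caps, mean)
cmp_cap <- group_compare(
  cap_mean$flux_cells_s[cap_mean$group == "hyperglycemic"],
  cap_mean$flux_cells_s[cap_mean$group == "euglycemic"])
cat(sprintf("flux comparison (capillary means): p = %.2f\n", cmp_cap$p))

# flux vs diameter, flux vs glucose
ok <- !caps$stalled
fd <- regression_r2_slope(caps$diameter_um[eu & ok],
                          caps$flux_cells_s[eu & ok])
cat(sprintf("flux ~ diameter (eu): slope %.1f cells/s/um, R2 %.2f\n",
            fd$slope, fd$r_squared))
wk_glu <- aggregate(glucose_mgdl ~ mouse_id + week, co$mice, mean)
wk_fx <- aggregate(flux_cells_s ~ mouse_id + week, caps, mean)
m <- merge(wk_glu, wk_fx)
fg <- regression_r2_slope(m$glucose_mgdl, m$flux_cells_s)
cat(sprintf("weekly flux ~ glucose: slope %.3f cells/s per mg/dL, R2 %.3f\n",
            fg$slope, fg$r_squared))

# young vs mature flux
caps$age <- age_group(caps$week)
yv <- group_compare(caps$flux_cells_s[eu & caps$age == "young"],
                    caps$flux_cells_s[eu & caps$age == "mature"])
cat(sprintf("young vs mature flux (eu): p = %.2f\n", yv$p))

# thickness contrast
th <- split(co$thickness$thickness_um, co$thickness$group)
tc <- group_compare(th$hyperglycemic, th$euglycemic)
cat(sprintf("thickness: hy %.2f vs eu %.2f um, p = %.2g\n",
            tc$mean[1], tc$mean[2], tc$p))

# grader agreement on a 38-capillary subset recounted by 5 graders
set.seed(2)
idx <- sample(which(caps$quality_index >= 3), 38)
truth <- caps$flux_cells_s[idx]
counts <- truth + matrix(rnorm(38 * 5, 0, 5), 38, 5)
colnames(counts) <- paste0("grader_", 1:5)
ba <- bland_altman(counts)
cat(sprintf("Bland-Altman: max |bias| %.2f cells/s, group LoA half-width %.2f cells/s\n",
            max(abs(ba$bias)), mean((ba$loa_high - ba$loa_low) / 2)))
write.csv(ba, file.path(out, "bland_altman.csv"), row.names = FALSE)
write.csv(weekly_summary(co, "flux_cells_s"),
          file.path(out, "flux_weekly.csv"), row.names = FALSE)
cat("statistics tables written under results/\n")
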