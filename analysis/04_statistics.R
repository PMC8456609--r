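#!/usr/bin/env Rscript
# Step 4 — inferential layer over the study tables.
#
# Reads the placement records written by 03_run_study.R and reports:
# (a) TOST equivalence of the ACJ-to-plate distances between repeat trials
#     and examiners at the 3 mm margin (simulated repeatability should land
#     well inside the margin, p << 0.05);
# (b) Steel-Dwass all-pairs comparisons of the contained-screw counts per
#     fragment size (counts are discrete and heavily tied, hence the rank
#     test);
# (c) Tukey HSD on the covered areas (the distal radial plate should
#     separate from both six-screw plates at p < 0.05).

library(clavsim)

out_dir <- "results"
pl <- read.csv(file.path(out_dir, "placements.csv"))
plates <- unique(pl$plate)

rep_tab <- read.csv(file.path(out_dir, "repeatability_table.csv"))
cat("TOST equivalence of ACJ distances (margin 3 mm):\n")
print(rep_tab[, c("plate", "comparison", "mean_abs_diff", "p_tost")],
      row.names = FALSE)

cat("\nSteel-Dwass p values for contained-screw counts per fragment size:\n")
sd_rows <- list()
for (fs in c(10, 15, 20, 25, 30)) {
  groups <- lapply(plates, function(p) pl[pl$plate == p,
                                          paste0("n_screws_", fs)])
  names(groups) <- plates
  tab <- steel_dwass(groups)
  for (i in 1:2) for (j in (i + 1):3) {
    sd_rows[[length(sd_rows) + 1]] <- data.frame(
      fragment_size = fs, plate_a = plates[i], plate_b = plates[j],
      p = tab$p[i, j])
  }
}
sd_tab <- do.call(rbind, sd_rows)
print(sd_tab, row.names = FALSE)
write.csv(sd_tab, file.path(out_dir, "steel_dwass_counts.csv"),
          row.names = FALSE)

cat("\nTukey HSD on covered areas:\n")
groups <- lapply(plates, function(p) pl$covered_area[pl$plate == p])
names(groups) <- plates
tk <- tukey_hsd(groups)
print(tk)
write.csv(as.data.frame(tk$p), file.path(out_dir, "tukey_areas.csv"))
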