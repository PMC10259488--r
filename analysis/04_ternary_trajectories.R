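#!/usr/bin/env Rscript
# Step 4 — pseudo-ternary choice geometry: per-mouse points and
# trajectories from water-vs-water to the 200 µg/ml condition, and the
# group-level apex distances that separate avoiders from non-avoiders.
# Also renders the diagram as an SVG.

suppressPackageStartupMessages(library(bottlechoice))

summaries <- read.csv("results/condition_summaries.csv")
ph <- read.csv("results/phenotypes.csv")
sched <- read_schedule("results/data/reference_schedule.yaml")

pts <- ternary_points(summaries)
write.csv(pts, "results/ternary_points.csv", row.names = FALSE)

lab <- setNames(ph$label, ph$mouse_id)
apexes <- group_apex_distances(pts, lab)
write.csv(apexes, "results/apex_distances.csv", row.names = FALSE)
message("Group mean distance to the 0%-consumption apex by condition:")
print(reshape(apexes[apexes$apex == "zero", c("group", "concentration",
                                              "mean")],
              idvar = "group", timevar = "concentration",
              direction = "wide"))

# per-mouse displacement from habituation to 200 µg/ml
conds <- unique(sched$condition_id)
disp <- do.call(rbind, lapply(split(pts, pts$mouse_id), function(p) {
  tr <- trajectory(p, condition_order = conds)
  data.frame(mouse_id = tr$mouse_id, t(tr$displacement))
}))
write.csv(disp, "results/trajectory_displacements.csv", row.names = FALSE)
avg <- aggregate(d_zero ~ unname(lab[disp$mouse_id]), disp, mean)
names(avg) <- c("group", "mean_d_zero_displacement")
message("Mean displacement of the distance to the zero apex:")
print(round(avg[2], 1))

# SVG of the diagram: habituation (small) and 200 µg/ml (large) points
s <- sqrt(3) / 2
svg("results/ternary_diagram.svg", width = 6, height = 5.5)
par(mar = c(1, 1, 2, 1))
plot(NA, xlim = c(-5, 105), ylim = c(-5, 95), asp = 1, axes = FALSE,
     xlab = "", ylab = "", main = "Choice geometry: habituation to 200 µg/ml")
polygon(c(0, 100, 50), c(0, 0, 100 * s), border = "grey40")
text(c(-2, 102, 50), c(-4, -4, 100 * s + 4),
     c("0% nic.", "100% nic.", "side biased"), cex = 0.8)
cols <- c(avoider = "#E8735C", non_avoider = "#5C8AE8")
for (cond in conds[c(1, length(conds))]) {
  pp <- pts[pts$condition_id == cond & !is.na(pts$x), ]
  points(pp$x, pp$y * s, pch = 19,
         cex = if (cond == conds[1]) 0.6 else 1.2,
         col = cols[lab[pp$mouse_id]])
}
legend("topright", bty = "n", pch = 19, col = cols,
       legend = c("avoider", "non-avoider"), cex = 0.8)
dev.off()
message("Diagram written to results/ternary_diagram.svg")
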