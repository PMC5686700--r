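#!/usr/bin/env Rscript
# Sensing two GnRH pulses: 15-min pulse, 135-min interval, 60-min pulse at
# the same concentration, across effector stabilities FL = 10, 100, 1000,
# 10,000 min (1000 cells x 4 concentrations each). Estimates per-pulse
# information, the additional information from the second pulse, and the MI
# between the pulse-1 and pulse-2 responses.
# Writes results/two_pulse.csv (and a figure if ggplot2 is available).

library(gnrhsense)

seed <- 1
dir.create("results", showWarnings = FALSE)

tp <- two_pulse_analysis(n_cells = 1000, seed = seed)
tab <- tp$table
write.csv(tab, "results/two_pulse.csv", row.names = FALSE)
print(tab[, c("fl", "I_z1_s", "I_z2_s", "additional", "I_z1_z2")],
      row.names = FALSE)

cat("\nAs effector lifetime grows, pulse-1 responses become predictive of\n")
cat("pulse-2 responses [I(Z1;Z2) rises toward ~2 bits] and the additional\n")
cat("information gained by sensing the second pulse decays toward zero.\n")
cat("Rapidly fluctuating effectors give the opposite: little memory, more\n")
cat("to learn from a second pulse.\n")

fig <- try({
  library(ggplot2)
  long <- rbind(
    data.frame(fl = tab$fl, quantity = "additional I(Z2;S|Z1)",
               bits = tab$additional, sd = tab$additional_sd),
    data.frame(fl = tab$fl, quantity = "I(Z1;Z2)",
               bits = tab$I_z1_z2, sd = tab$I_z1_z2_sd))
  gg <- ggplot(long, aes(log10(fl), bits, colour = quantity)) +
    geom_point() + geom_line() +
    geom_errorbar(aes(ymin = bits - sd, ymax = bits + sd), width = 0.05) +
    labs(x = "log10 fluctuation lifetime (min)", y = "bits",
         title = "Two-pulse sensing vs effector stability") +
    theme_minimal()
  ggsave("results/two_pulse.pdf", gg, width = 6, height = 4)
}, silent = TRUE)
if (inherits(fig, "try-error")) cat("(figure skipped)\n")
cat("Wrote results/two_pulse.csv\n")
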