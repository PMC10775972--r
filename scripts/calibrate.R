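#!/usr/bin/env Rscript
# Re-derives the calibrated default parameter set of the package.
#
# The structure (which parameters depart from the unity-style starting
# point, and why) is fixed by the design reasoning laid out in the package
# vignette; this script pins the two quantitative dials that the anchors
# determine numerically:
#   * bm21  — bisected so the deterministic b21 sweep loses bistability
#             between 0.79 and 0.80 (threshold 0.8 on a 0.01 grid);
#   * D     — bisected so the juvenile-to-flowering MFPT at 430 ppm sits
#             in the 70-80 day window;
# and then verifies the remaining anchors: ~10% earlier flowering at
# 810 ppm, ~20-day advance when the SPL -> miR156 feedback is removed
# (400-800 ppm, paired seeds), and the knockout basin topology.
#
# Usage: Rscript scripts/calibrate.R [--full]
#   default: verification at reduced ensemble sizes (~10 min);
#   --full:  calibration-grade sizes as used to fix the shipped defaults.

suppressPackageStartupMessages(library(flowerscape))

full <- "--full" %in% commandArgs(trailingOnly = TRUE)
n_fpt <- if (full) 1200 else 400

structure_overrides <- list(
  a12 = 0.080,  # SPL -> miR156 share: ~20-day advance when removed
  a14 = 1.24,   # AP2 -> miR156 carries the juvenile state
  a32 = 1.09,   # SPL -> miR172 relay
  bm34 = 1.58,  # AP2 -| miR172 dynamic range
  bm43 = 2.84,  # miR172 -| AP2: juvenile AP2 branch above threshold
  bm44 = 0.60,  # AP2 self-repression: flowering AP2 branch below threshold
  b = 0.90,     # partial CO2 depth: CO2-independent miR156 floor
  bm = 1.29,    # max rate of the CO2-responsive miR156 branch
  c = 0.0074,   # CO2 half-effect near 140 ppm
  svp = 0.5)    # sub-threshold constant SVP input

base_with <- function(...) do.call(flowering_params,
                                   c(structure_overrides, list(...)))

is_bistable <- function(p, n_starts = 40, seed = 2) {
  fps <- find_fixed_points(p, n_starts = n_starts, seed = seed)
  sum(fps$stability == "stable") >= 2
}

## 1. pin bm21 against the b21 threshold -----------------------------------
loss_point <- function(p) {
  for (b21 in seq(0.88, 0.70, by = -0.005)) {
    q <- p; q["b21"] <- b21
    if (!is_bistable(q)) return(b21)
  }
  NA
}
lo <- 2.6; hi <- 3.6
for (it in 1:9) {
  mid <- (lo + hi) / 2
  lp <- loss_point(base_with(bm21 = mid))
  cat(sprintf("bm21 = %.3f -> bistability lost at b21 = %.3f\n", mid, lp))
  if (is.na(lp) || lp < 0.7955) lo <- mid else hi <- mid
}
bm21 <- round((lo + hi) / 2, 3)
cat("pinned bm21 =", bm21, "\n")

## 2. pin D against the 430 ppm MFPT window --------------------------------
mfpt_at <- function(D, n = n_fpt) {
  p <- base_with(bm21 = bm21, D = D)
  summarize_fpt(first_passage_ensemble(p, n_traj = n, T_max = 2000,
                                       seed = 99))$mfpt
}
loD <- log(0.03); hiD <- log(0.10)
for (it in 1:8) {
  D <- exp((loD + hiD) / 2)
  m <- mfpt_at(D)
  cat(sprintf("D = %.4f -> MFPT(430) = %.1f days\n", D, m))
  if (is.na(m) || m > 74) loD <- log(D) else hiD <- log(D)
}
D <- round(exp((loD + hiD) / 2), 4)
cat("pinned D =", D, "\n")

p <- base_with(bm21 = bm21, D = D)

## 3. verify the remaining anchors ------------------------------------------
m430 <- summarize_fpt(first_passage_ensemble(p, n_traj = n_fpt,
                                             T_max = 2000, seed = 7))$mfpt
p810 <- p; p810["co2"] <- 810
m810 <- summarize_fpt(first_passage_ensemble(p810, n_traj = n_fpt,
                                             T_max = 2000, seed = 7))$mfpt
cat(sprintf("MFPT(430) = %.1f d; MFPT(810) = %.1f d; advance = %.1f%%\n",
            m430, m810, 100 * (m430 - m810) / m430))

adv <- vapply(c(400, 600, 800), function(co2) {
  pb <- p; pb["co2"] <- co2
  pk <- knockout(pb, "a12")
  summarize_fpt(first_passage_ensemble(pb, n_traj = n_fpt, T_max = 2000,
                                       seed = 11))$mfpt -
    summarize_fpt(first_passage_ensemble(pk, n_traj = n_fpt, T_max = 2000,
                                         seed = 11))$mfpt
}, numeric(1))
cat(sprintf("a12-knockout advance (400/600/800 ppm): %.1f/%.1f/%.1f, mean %.1f d\n",
            adv[1], adv[2], adv[3], mean(adv)))

for (nm in c("a14", "b34")) {
  stopifnot(!is_bistable(knockout(p, nm)))
  cat("knockout", nm, "-> juvenile basin lost (monostable) ok\n")
}
stopifnot(is_bistable(knockout(p, "a12")), is_bistable(knockout(p, "b44")))
cat("knockouts a12, b44 -> still bistable ok\n")

out <- file.path("scratch", "calibrated_params.yaml")
dir.create("scratch", showWarnings = FALSE)
write_params(p, out)
cat("calibrated parameter set written to", out, "\n")
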