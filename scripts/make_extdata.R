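#!/usr/bin/env Rscript
# Regenerates the synthetic fixtures shipped under inst/extdata/.
#
# All files are SYNTHETIC stand-ins that emulate the statistical structure of
# the East African carnivore study inputs: a two-guild occurrence table with
# the study's bookkeeping (279 occurrences, 88 species, 9 extant), and dated
# proxy measurement tables for the five temporal predictors. They are
# generated entirely by the package's own simulators with fixed seeds.
#
# Run from the repository root:  Rscript scripts/make_extdata.R

suppressMessages(library(paleocarn))
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
grid <- seq(0, 4, by = 0.01)

## ---- proxy truths -------------------------------------------------------
# Hominin brain volume: logistic growth from under 500 cm3 (4 Ma) to about
# 1500 cm3 (present).
brain_truth <- function(t) 500 + 1000 / (1 + exp((t - 2) / 0.45))
# Forest cover: declining fraction constructed so that its squared
# correlation with the brain truth on the grid is 0.87 (the two real curves
# are tightly coupled; that coupling is part of the structure emulated here).
b <- brain_truth(grid)
bz <- (b - mean(b)) / sd(b)
g <- sin(2 * pi * grid / 4)                      # smooth orthogonal component
g <- g - mean(g) - bz * sum((g - mean(g)) * bz) / sum(bz^2)
gz <- g / sd(g)
fz <- -(sqrt(0.87) * bz + sqrt(0.13) * gz)       # cor(fz, bz)^2 = 0.87
forest_vals <- 0.45 + 0.12 * fz                  # fraction-of-forest scale
forest_truth <- approxfun(grid, forest_vals, rule = 2)
temp_truth <- function(t) 23.5 + 0.4 * t - 0.15 * sin(2 * pi * t / 3)  # deg C
precip_truth <- function(t) 900 + 75 * t + 30 * cos(2 * pi * t / 2.5)  # mm/yr
wdef_truth <- function(t) 450 - 60 * t + 25 * sin(2 * pi * t / 2)      # mm/yr

proxies <- list(
  brain = list(f = brain_truth, sd = 50, n = 42, h = 0.25),
  forest = list(f = forest_truth, sd = 0.04, n = 48, h = 0.25),
  temperature = list(f = temp_truth, sd = 0.5, n = 40, h = 0.2),
  precipitation = list(f = precip_truth, sd = 60, n = 40, h = 0.2),
  water_deficit = list(f = wdef_truth, sd = 40, n = 36, h = 0.2)
)
for (nm in names(proxies)) {
  p <- proxies[[nm]]
  m <- simulate_proxy(p$f, n_points = p$n, dating_half_width = p$h,
                      noise_sd = p$sd, seed = derive_seed(424, match(nm, names(proxies))))
  write_proxy(m, file.path("inst/extdata",
                           paste0("synthetic_proxy_", nm, ".tsv")))
  cat("wrote", nm, "\n")
}

## ---- occurrence table ---------------------------------------------------
# Large guild: extinction driven by the brain curve (exponential link);
# small guild: constant extinction. Simulated records are then thinned to
# the study's bookkeeping: 88 species (44 large / 44 small), 9 extant
# (4 large / 5 small), 279 occurrences.
brain_curve <- new_predictor_curve(grid, brain_truth(grid), scale = TRUE)
lg <- simulate_fossil_record(
  sim_config(seed = 9001, n_species_target = 45, lambda0 = 0.25,
             mu_model = mu_covariate("exponential", mu0 = 0.3, gamma = 1.2,
                                     curve = brain_curve),
             q = 2, age_error_width = 0.3),
  size_class = "large")
sm <- simulate_fossil_record(
  sim_config(seed = 9002, n_species_target = 45, lambda0 = 0.22,
             mu_model = mu_constant(0.4), q = 2, age_error_width = 0.3),
  size_class = "small")
lg$occurrences$species <- paste0("L_", lg$occurrences$species)
sm$occurrences$species <- paste0("S_", sm$occurrences$species)

pick_species <- function(occ, n_extant, n_extinct, seed) {
  sp <- occ[!duplicated(occ$species), c("species", "extant")]
  set.seed(seed)
  ext <- sample(sp$species[sp$extant], n_extant)
  dead <- sample(sp$species[!sp$extant], n_extinct)
  occ[occ$species %in% c(ext, dead), ]
}
occ <- rbind(pick_species(lg$occurrences, 4, 40, 31),
             pick_species(sm$occurrences, 5, 39, 32))

# thin occurrences (never below one per species) to exactly 279 rows
set.seed(33)
target <- 279
stopifnot(nrow(occ) >= target)
while (nrow(occ) > target) {
  counts <- table(occ$species)
  removable <- which(counts[occ$species] > 1)
  occ <- occ[-sample(removable, 1), ]
}
occ <- occ[order(occ$species, -occ$age_max), ]
s <- occurrence_summary(occ)
stopifnot(s$n_occurrences == 279, s$n_species == 88, s$n_extant == 9)
write_occurrences(occ, "inst/extdata/synthetic_occurrences.tsv")
cat(sprintf("occurrences: %d rows, %d species (%d large / %d small), %d extant\n",
            s$n_occurrences, s$n_species, s$n_large, s$n_small, s$n_extant))
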