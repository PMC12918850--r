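# filamentr

Tools for two recurring analyses in amyloid structural biology, built
around tau filaments:

1. **Filament fold comparison.** Given single protofilament rungs of two
   filament folds, compute the backbone RMSD over *every* contiguous
   window of aligned residues, with an independent optimal (Kabsch)
   superposition per window. Two folds can be globally dissimilar yet
   share a motif whose internal geometry is conserved while its
   orientation has rotated; per-window fitting finds it where a single
   global superposition cannot. The mean over all windows — the
   **localized RMSD** — summarises similarity, the full matrix renders as
   a triangular heat-map, and localized RMSDs rank a query fold against a
   library of disease-associated folds.
2. **ThT fibrillization kinetics.** Background-subtract plate-reader
   Thioflavin T time courses, fit the Gompertz function
   `y(t) = A·exp(−exp(−(t − t_i)/B))` by Levenberg–Marquardt least
   squares, derive the apparent elongation rate `k_app = 1/B` and the
   aggregation propensity `1/t½` with `t½ = t_i − B·ln(ln 2)`, and apply
   QC discard rules for low-signal and bubble-artifact wells.

A synthetic helical-filament generator (rise / twist / crossover
geometry, `crossover = 180·rise/|twist|`) and a seeded kinetics simulator
make every stage testable without downloading depositions.

Intended users: structural biologists comparing cryo-EM filament models
(PDB/mmCIF, canonical 2N4R tau numbering) and biochemists analysing
aggregation assays.

## Worked example

Compare a synthetic 100-residue rung against a copy carrying a 3 Å
deformation over residues 320–340:

```r
library(filamentr)

rung <- serpentine_rung()                       # 100-residue CA rung, numbered from 273
pert <- perturb_region(rung, c(320, 340), amplitude = 3, seed = 7)

m <- window_rmsd_matrix(rung, pert, min_window = 3, atom_set = "CA")
nrow(m)                                         # 4851 windows
localized_rmsd(m)                               # 0.5283 Å
region_rmsd(rung, pert, start_res = 320, end_res = 340)   # 1.0108 Å
region_rmsd(rung, pert, start_res = 273, end_res = 310)   # 0 (untouched region)
render_heatmap(m, "heatmap.png")                # triangular PNG + SVG

rank_folds(rung, list(self = rung, bumped = pert))
#>    label localized_rmsd n_windows comparable
#> 1   self   3.211038e-15      4851       TRUE
#> 2 bumped   5.282660e-01      4851       TRUE
```

The localized RMSD of 0.53 Å is the mean over all 4,851 windows; windows
that do not overlap the deformed range score ~0, so the heat-map shows a
single elevated patch over starts 320−length…340. Helical geometry round
trip at the tau scale (4.8 Å rise, 600 Å crossover):

```r
p <- helical_params(rise = 4.8, twist = crossover_to_twist(600, 4.8, "left"))
#> <helical_params> rise 4.8000 A, twist -1.4400 deg/rung (left-handed), crossover 600.0 A
fil <- build_filament(rung, p, n_rungs = 9)
estimate_helical_params(fil)                    # recovers rise 4.8, twist -1.44
```

And a kinetics fit on a simulated noisy well (A = 100 RFU, t_i = 10 h,
B = 2 h, 5-min sampling over 24 h, 2% noise):

```r
cv  <- simulate_tht(A = 100, t_i = 10, B = 2, noise_sd = 2, seed = 42)[[1]]
fit <- fit_gompertz(subtract_background(cv))
#> <gompertz_fit> well sim01: A=99.1 RFU, t_i=10.1 h, B=1.98 h (k_app=0.504 /h, t_half=10.8 h), mse=4.04
aggregation_propensity(fit)                     # 0.0927 1/h
```

`k_app = 0.504 /h` recovers the true `1/B = 0.5 /h` to under 1%.

## Command line

A thin CLI wraps the same functions with identical defaults
(`inst/cli/filamentr.R` after installation):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/filamentr.R", package="filamentr"))')" \
  compare typeI.cif typeII.cif --atoms CA --min-window 3 --out-dir out/
```

Subcommands: `compare`, `rank`, `heatmap`, `build`, `perturb`, `tht-fit`,
`tht-sim`. Every run writes a provenance JSON; fixed inputs and seed give
byte-identical tabular outputs.

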