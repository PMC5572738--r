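# scramblr

Quantitative analysis of phospholipid scramblase assays on reconstituted
proteoliposomes.

Membrane-protein biochemists use the dithionite assay to test whether a
protein scrambles lipids: vesicles carry a trace of NBD-labelled reporter
lipid, and membrane-impermeant dithionite bleaches only the outer-leaflet
pool. Protein-free vesicles lose ~50% of their fluorescence; vesicles with
at least one active scramblase lose (ideally) all of it. Titrating the
protein-to-phospholipid ratio (PPR) then measures the fraction of vesicles
carrying ≥1 functional scramblase — and the shape of that curve encodes the
molar mass of the functional unit, since heavier units mean fewer copies
per gram of protein.

`scramblr` implements the full analysis:

* **Occupancy model.** Poisson placement of scramblase units with mean
  λ(r) = (α/2)·PPR\*·r², averaged in closed form over a Gaussian vesicle
  size distribution:

  P(≥1) = 1 − (1 + σ²αPPR\*)^(−1/2) · exp(−(r̄²·PPR\*·α/2)/(1 + σ²αPPR\*)),

  with PPR\* = PPR/f correcting for the vesicle pool refractory to
  reconstitution (f = 0.524 by default). The fit constant converts to the
  functional molar mass via M = 16π/(A·α), A the area per lipid
  (0.70 nm²).
* **Endpoint transform.** P = (F − F₀)/(Fmax − F₀) anchors the titration
  between the protein-free (43.0%) and saturating (76.2%) endpoints.
* **Kinetics.** Single-exponential fits of the post-addition decay;
  scrambling-rate lower bound (ln2/t½)·N_lipids.
* **Size distribution.** Gaussian fits of DLS radius samples or
  histograms.
* **Proton pumping.** Pyranine fluorescence ↔ pH conversion via a linear
  calibration, with light-schedule-aware simulators.
* **Seeded simulators** for every input the pipeline consumes, so all of
  the above can be validated on synthetic data with known truth.

## Worked example

Simulate a 20-point titration from a known functional mass of
80,800 g/mol (a trimer of a ~27 kDa monomer), then solve the inverse
problem:

```r
library(scramblr)

ser <- generate_ppr_series(seq(0.05, 1.5, length.out = 20),
                           M_true = 80800, noise_sd = 0.02, seed = 42)
fit <- fit_occupancy_model(ser)
fit
#> Occupancy model fit (gaussian, 20 points)
#>   alpha = 9.274e-04 +/- 3.92e-05 mol g^-1 nm^-2
#>   functional mass M = 77429 +/- 3270 g/mol
```

The fitted α is the occupancy constant; its inverse-proportional
conversion gives the mass of the functional unit, here recovered within
one standard error of the generating 80,800 g/mol (noise sd 0.02 on the
probability scale is realistic for endpoint assays; averaging over seeds
recovers the truth to well under 5%).

Reduction kinetics bound the scrambling rate from below — a ~15 s
half-life over a ~3.5×10⁵-lipid vesicle implies

```r
scrambling_rate_lower_bound(15.2, lipids_per_vesicle(vesicle_geometry(100.6)))
#> [1] 15924.15
```

i.e. >10⁴ lipids per second per functional unit. A synthetic DLS sample
refits its generating Gaussian:

```r
fit_gaussian_radii(simulate_dls(1e4, 100.6, 31.5, seed = 42)$radii)
#> Gaussian size fit (mle, n = 10000): r_bar = 100.3 +/- 0.32 nm, sigma = 31.6 +/- 0.22 nm
```

The end-to-end pipeline (DLS fit → endpoint transform → occupancy fit →
mass) runs from CSV inputs via `run_full_pipeline()`, and
`run_simulate()` writes seeded fixture files with a JSON manifest. A thin
command-line wrapper over the same functions lives at
`inst/cli/scramblr.R` (subcommands `simulate`, `analyze`, `fit`,
`pipeline`).

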