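# btpcorr

Linear vs. nonlinear correlation screening for protein backbone torsional
pairs.

## The problem

Correlated backbone motion — especially between residues far apart in space —
is a candidate carrier of allosteric signals. The natural coordinates are
the backbone dihedrals φ/ψ: a chain of N residues has 2N−2 defined torsions
(indexed ψ₁, φ₂, ψ₂, …, φ_N), and any unordered pair of them is a *backbone
torsional pair* (BTP). For every BTP the package computes, from a torsion
time series (an MD trajectory's dihedrals, or synthetic data):

- the **Fisher–Lee circular correlation**
  r = Σ sin(xᵢ−x̄) sin(yᵢ−ȳ) / √(Σ sin²(xᵢ−x̄) · Σ sin²(yᵢ−ȳ)),
  with instability flags for the antipodal two-state case where the
  circular mean is noise;
- the **mutual information** MI = Sₓ + S_y − S_xy from 60×60-bin histograms
  over the 2-torus (nats; k_B units of entropy);
- the **MPMI contour** f(r) = −a·ln(1 − |r|^b) — the maximum possible MI
  attributable to a linear correlation of magnitude r — calibrated so that
  f(0.4)−f(0.1) = 0.08 and f(0.7)−f(0.4) = 0.23 nats
  (a = 0.4465939, b = 1.9060437);
- the **linear/nonlinear** label (nonlinear ⇔ MI − f(r) > 0.02 nats) and the
  **DSP/SMP/DMP** torsional-state class from cyclic collective-bin peak
  counting of each marginal;
- supporting diagnostics: K-L–divergence convergence checks across
  trajectory thirds, permutation nulls for the plug-in MI bias,
  trajectory-subset analysis, snapshot thinning, and a heterogeneity score
  that tests whether the same-signed peaks of Δp = p(x,y) − p(x)p(y) lie on
  one straight line (homogeneous linear coupling) or need several
  (heterogeneous — the mechanism behind nonlinear BTPs).

Because MD trajectories of meaningful length are not distributable, the
package includes a first-class synthetic generator (von Mises state
mixtures, Markov state switching, per-state Gaussian-copula coupling,
pseudo-geometry and DSSP-style labels) with analytic ground truth, used by
the whole validation suite.

## Worked example

Simulate a 10-residue "protein" (20 000 snapshots) with three planted
couplings — one linear (Gaussian-copula, ρ = 0.5), one state-coupled
(V-shaped 3→2 state mapping) and one heterogeneous (opposite within-state
slopes) — then run the full pipeline:

```r
library(btpcorr)
library(dplyr)

couplings <- tibble::tibble(
  i = c(2, 8, 14), j = c(11, 17, 5),
  type = c("copula", "state", "heterogeneous"), rho = c(0.5, 0.5, 0.8)
)
protein <- sample_protein(10, m = 20000, seed = 42, couplings = couplings)
report <- run_pipeline(protein$torsions, structure = protein$structure,
                       ss = protein$ss, config = analysis_config(seed = 7))
report
#> <btp_report> 153 pairs: 30 nonlinear (19.6%), max MI = 0.7097 nats
#>   convergence: 27.8% of torsions not converged

report$pairs |> filter(linearity == "nonlinear") |> arrange(desc(excess)) |>
  select(i, j, r, mi, mpmi, excess, transition_class, pair_type, distance) |>
  head(3)
#> # A tibble: 3 × 9
#>       i     j       r    mi     mpmi excess transition_class pair_type distance
#>   <int> <int>   <dbl> <dbl>    <dbl>  <dbl> <chr>            <chr>        <dbl>
#> 1     8    17 -0.564  0.710 0.183     0.527 DMP              ab-ab         16.5
#> 2     5    14 -0.0522 0.488 0.00161   0.486 SMP              ab-ab         17.9
#> 3     1     8 -0.0342 0.112 0.000719  0.111 DMP              ab-L          14.2
```

The two strongest nonlinear pairs are exactly the planted state-coupled
(8, 17) and heterogeneous (5, 14) couplings: both carry large MI at modest
|r|, far above the contour. The classification table crosses the
linear/nonlinear label with the torsional-state classes — nonlinear pairs
concentrate in DMP, while every DSP pair is linear:

```r
report$classification
#> # A tibble: 6 × 4
#>   transition_class linearity     n percent
#> 1 DSP              linear       55    35.9
#> 2 DSP              nonlinear     0     0
#> 3 SMP              linear       67    43.8
#> 4 SMP              nonlinear    10     6.5
#> 5 DMP              linear        1     0.7
#> 6 DMP              nonlinear    20    13.1
```

`report$strata` splits the same counts by pair type (helix/strand pooled as
"ab" vs loop "L") and by distance at the inclusive 8 Å cutoff between
central-bond midpoints; `report$permutation` gives the spurious-correlation
floor (here max permuted MI = 0.047 nats — everything classified nonlinear
is far above it); `report$convergence` is the per-torsion K-L report (the
multi-state loop torsions of this short synthetic trajectory are the
non-converged ones). `plot_mi_r(report$pairs)` draws the MI-vs-r scatter
with the contour; `write_report(report, dir)` emits the full TSV/JSON
bundle, byte-identical under a fixed seed.

`inst/scripts/btp-tools.R` wraps the same functions as a CLI with
subcommands `extract` (PDB → torsion TSV), `analyze`, `simulate` and
`diagnose`.

## Package tour

| area | functions |
|---|---|
| geometry | `dihedral_angle`, `build_torsion_index`, `extract_torsion_series`, `torsion_position`, `torsion_distances`, `map_secondary_structure`, `pair_type` |
| distributions | `histogram_1d`, `joint_histogram`, `count_peaks_1d`, `count_joint_peaks`, `distribution_difference`, `heterogeneity_score` |
| correlation | `circular_mean`, `circular_correlation`, `entropy`, `mutual_information`, `calibrate_contour`, `mpmi_contour`, `fit_contour`, `classify_linearity`, `classify_transition_status` |
| diagnostics | `kl_divergence`, `convergence_check`, `permutation_null`, `subset_analysis`, `thin_snapshots` |
| synthetic data | `state_model`, `pair_spec`, `sample_pair`, `sample_heterogeneous_pair`, `sample_protein`, `planted_design` |
| pipeline | `analysis_config`, `analyze_pairs`, `run_pipeline`, `classification_table`, `stratify_pairs`, `correlation_matrices`, `write_report` |
| I/O | `read_torsion_tsv`/`write_torsion_tsv`, `read_dssp_codes`, `read_structure`/`write_structure`, `write_grid_tsv` |

Result objects are tibbles with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` views. The methods vignette
(`vignettes/btp-correlations.Rmd`) documents the model, every tunable
parameter, the generator's scope and the numerical edge cases.
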