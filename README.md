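# iondetail

Nanodosimetry asks what a charged-particle track does at the scale of the DNA
double helix: how many ionizations land inside a cylinder a few nanometres
across per particle traversal. The probability distribution of that count —
the **ionization cluster size distribution (ICSD)**, `P_ν` — carries more
biological information than macroscopic dose or LET, because DNA double-strand
breaks need at least two nearby lesions.

`iondetail` computes the nanodosimetric statistics of ICSDs and links them to
cell-survival radiobiology:

* **M1** = Σ ν·P_ν — mean cluster size, a geometrically restricted analogue of
  LET;
* **Fk** = Σ_{ν≥k} P_ν — probability of a cluster of size ≥ k, the classical
  radiation-quality parameter;
* **R2(p)** = Σ_ν P_ν · w(ν, p) with
  `w(ν, p) = 1 − (1−p)^ν − ν p (1−p)^{ν−1}` — the probability that at least
  two sub-lethal lesions arise when each ionization independently becomes a
  lesion with probability `p`. R2 replaces Fk's hard step in ν by a smooth,
  biologically interpretable weight; it reduces exactly to F2 at `p = 1`, and
  it is *measurable*: binomially thinning a spectrum with detector efficiency
  η = p and taking F2 equals R2(p) on the true spectrum (`thin_icsd()`).

On the radiobiology side the package evaluates the linear-quadratic survival
model `−ln S = αD + βD²`: iso-survival doses, RBE at 5% survival, the
negative-β correction for database fits, and the **inactivation cross
section**

```
σ_S = (k/ρ) · LET · sqrt(α² − 4 β ln S),   k = 0.1602, σ in µm², LET in keV/µm
```

The two sides meet in `grid_fit()`, which fits the proportional model
**σ ≈ K · R2(p; d)** by scanning lesion probability `p` and target diameter
`d` and minimizing an (unweighted) sum-of-squares χ², with the scale `K`
solved in closed form per grid cell. A toy track-segment Monte Carlo and an
analytic compound-Poisson generator (`simulate_icsd()`,
`synthetic_icsd_table()`, `generate_survival_dataset()`) provide complete
synthetic studies with known ground truth, so the whole pipeline is testable
end to end.

## Worked example

```r
library(iondetail)

# an overdispersed ICSD: Poisson primaries, geometric secondary clusters
x <- parametric_icsd("compound_poisson", mean_primaries = 2, multiplicity_mean = 0.6)
m1(x)                      # 3.2
fk(x, 2:5)                 # 0.6955 0.5263 0.3792 0.2623
r2(x, p = c(0.35, 1))      # 0.3006 0.6955   (p = 1 recovers F2)
fk(thin_icsd(x, 0.35), 2)  # 0.3006          (measured F2 at efficiency 0.35 = R2(0.35))

# closed-loop synthetic study: truth sigma = 57 um^2 * R2(0.35; 2.3 x 3.4 nm)
res <- cmd_synth_study(n_records = 60, sigma_log = 0.15, seed = 2,
                       energies = 10^seq(log10(0.3), 2.8, length.out = 15),
                       p_grid = seq(0.2, 1, 0.05))
res$fit
#> <icsd_fit> sigma ~ K * R2(p; d)
#>   best: p = 0.5, d = 2 x 2.96 nm, K = 58.23 um^2 (chi2 = 2180, 60 records)
#>   R^2 = 0.934; surface: 68 cells, 1 tie at the minimum
```

The noisy 60-record fit lands on `(p = 0.5, d = 2 nm)` rather than the true
`(0.35, 2.3 nm)` — the χ² surface has a shallow valley running from small
`p`/large `d` to large `p`/small `d`, so neighbouring combinations fit almost
equally well; `K` is stable (58.2 vs the true 57 µm²). With noise-free records
or the target size held fixed the truth is recovered exactly
(`grid_fit(recs, grid, d_list = 2.3)`). `autoplot(res$fit)` draws the
normalized χ² heatmap; `tidy()`/`glance()` give broom-style summaries, and
`res$fit$model_comparison` shows the R2-based model out-correlating every
single-Fk proportional model on R2-generated data.

A thin CLI wraps the same functions:
`Rscript inst/cli/iondetail.R stats --icsd icsd.csv --out grid.csv`
(subcommands `stats`, `simulate`, `fit`, `rbe`, `synth-study`).

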