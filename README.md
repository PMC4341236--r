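# conduitpcp

Planar cell polarity (PCP) at subcellular resolution in the *Drosophila*
larval epidermis, as a testable simulation.

The ventral abdominal segment of the second/third-stage larva carries about
seven rows of large (~30 µm) denticulate cells (rows 0–6) and two rows of
tendon cells (T1, between rows 1 and 2; T2, between rows 4 and 5).
Denticles of rows 0, 1 and 4 point forwards, rows 2, 3, 5 and 6 point
backwards. The polarity machinery is the Dachsous/Fat system: the atypical
protocadherins Ds and Ft form intercellular heterodimer bridges
(Ds<sup>x</sup>–Ft<sup>y</sup> and Ft<sup>x</sup>–Ds<sup>y</sup> between
cells *x* and *y*), and the Golgi kinase Four-jointed (Fj) tunes their
binding activity (activating Ft, deactivating Ds). A cell points its
denticles towards the membrane carrying more of its own Ft in bridges —
i.e. towards the neighbour presenting more Ds.

The package's core claim is the *conduit* model: the Ds/Ft comparison is not
made cell-wide but locally, between **facing anterior and posterior membrane
subregions** linked by oriented intracellular conduits. When the two
subregions of one cell face neighbours of different types, the subdomains
polarise independently — a single cell becomes **multipolar**. The package
implements the full chain:

1. **Synthetic tissue** — brick-lattice cell maps of a hemisegment, plus the
   perturbed anatomies: atypical (tilted, two-row-spanning) cells, breaches
   in the tendon rows, *ds⁻ ft⁻* tissue, and 1–5-cell Ds-overexpressing
   clones (`build_segment_map()`, `insert_atypical_cell()`,
   `insert_tendon_gap()`, `mark_clone()`).
2. **Activity landscape** — per-row Ds/Ft/Fj expression and Fj-modulated
   activities: `ds_act = ds·/(1+α·fj)`, `ft_act = ft·(1+β·fj)`
   (`assign_expression()`, `compute_activities()`, `apply_genotype()`).
3. **Bridge allocation** — per-cell protein pools spread over discretised
   membrane segments, relaxed to a deterministic fixed point of a
   bind/unbind + shuttle iteration with exact per-cell conservation
   (`initialise_bonds()`, `relax_bonds()`).
4. **Conduit readout** — each cell is sliced into 5 µm mediolateral bands;
   a band's score is the own-Ft share of bridges on its posterior membrane
   minus that on its anterior membrane; calls are anterior / posterior /
   unpolarized (`build_conduits()`, `score_conduits()`, `classify_cells()`,
   `place_denticles()`).
5. **Quantitation** — denticles classed by the neighbour type their domain
   abuts (tendon / non-tendon / intermediate), 2×2 contingency tables with
   the ambiguous-denticle allocation conventions, and a first-principles
   two-sided Fisher exact test with an exact rational-arithmetic
   cross-check (`classify_denticle_domain()`, `build_table()`,
   `fisher_exact()`, `fisher_exact_rational()`).

The published atypical-cell contingency tables ship as a plain-text fixture
(`inst/extdata/table1.json`, `load_table1()`).

## Worked example

```r
library(conduitpcp)

run <- run_scenario(scenario_config("atypical_row4", seed = 1))
run
#> <run_result> atypical_row4 (seed 1): 55 cells, 212 conduits, 212 denticles
#>   classes: multipolar=1 unipolar_anterior=14 unipolar_posterior=20 unpolarized=10

at <- run$map$cells$id[run$map$cells$is_atypical]
unique(run$conduits[run$conduits$cell == at,
                    c("ant_labels", "post_labels", "call")])
#>     ant_labels post_labels      call
#> 127          3          T2  anterior
#> 133          3           4 posterior
```

The one atypical cell is multipolar: the subdomain whose posterior membrane
abuts the low-Ds T2 tendon cell points its denticles forwards, while the
subdomain abutting a high-Ds normal row 4 cell points backwards — each
conduit orients towards the side presenting more Ds. Its row 3 and row 4
neighbours keep their normal calls (`unipolar_posterior`,
`unipolar_anterior`).

The exact test reproduces the published mutant statistics:

```r
fisher_exact(matrix(c(16, 21, 14, 13), 2, byrow = TRUE))  # 0.6134927
fisher_exact(matrix(c(54, 37, 24, 20), 2, byrow = TRUE))  # 0.7103687
fisher_exact(matrix(c(110, 8, 8, 41), 2, byrow = TRUE))   # 6.3e-23
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that generate every
result table and figure under `results/`:

| script | what it shows |
|---|---|
| `01_build_tissues.R` | builds and serialises all scenario cell maps |
| `02_wildtype_polarity.R` | row-by-row wild-type polarity pattern |
| `03_atypical_multipolarity.R` | multipolar atypical row 4 cell; unipolar row 2/3 |
| `04_mutant_indeterminacy.R` | *ds⁻ ft⁻* orientation independent of neighbours |
| `05_clones_and_gaps.R` | clone repolarisation; tendon-gap indeterminacy |
| `06_table1_stats.R` | exact statistics of the published 2×2 tables |

Run them from the repository root, e.g.
`Rscript analysis/02_wildtype_polarity.R`.

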