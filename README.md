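# psdfrag

Statistical analysis of intact-protein fragmentation efficiency under
MALDI-TOF-TOF post-source decay (PSD).

Singly charged protein ions fragmenting by PSD cleave preferentially on
the C-terminal side of aspartate (D), glutamate (E) and asparagine (N)
residues — the *aspartic-acid effect* — with strong enhancement when the
next residue is proline or glycine. `psdfrag` is for mass spectrometrists
and structural bioinformaticians who want to quantify that efficiency per
cleavage site and relate it to sequence and structural properties of the
protein.

The pipeline:

1. **Fragment prediction** — singly protonated *average-mass* b/y ions for
   every internal D/E/N site, with ammonia/water-loss satellites.
2. **Signal scoring** — each predicted ion is matched to the most intense
   centroid peak within ±5 m/z; per site the fragment signal *u* is the
   larger of the b/y parent intensities and the signal score is
   `score = u / σ_background`, with σ the sample standard deviation of all
   unassigned peak intensities.
3. **Property extraction** from predicted structures (pLDDT ≥ 70):
   backbone/side-chain hydrogen-bond counts (2.5–3.2 Å), salt bridges
   (< 4.0 Å to K/R side-chain nitrogens), Kabsch–Sander 8-state secondary
   structure, Shrake–Rupley relative solvent accessibility, and eight
   centralities of the Cα residue-interaction network (contact ≤ 7 Å,
   unit edge weights).
4. **Statistics** — per residue class, negative-binomial (NB2, log-link)
   regression of scores on the 0–1-scaled numeric properties
   (`log μ = β0 + Σ βi xi`), with a likelihood-ratio test against the
   null; Kruskal–Wallis and pairwise Mann–Whitney tests for categorical
   properties; eCDF tail fractions and between-class eCDF correlation.

A synthetic-data generator produces sequences, backbone-complete
structures and centroided spectra with known ground truth, so every layer
is testable without external data.

## Worked example

Score the D/E/N sites of one protein against its spectrum:

```r
library(psdfrag)
seq1 <- generate_sequence(40, site_quota = c(D = 2, E = 1, N = 1), seed = 42)
gen  <- generate_spectrum(seq1, beta0 = log(8), sigma_bg = 2,
                          n_background = 150, seed = 43)
score_protein(seq1, gen$spectrum, "demo")
#>   protein_id position residue nterm_neighbor cterm_neighbor winning_series  u
#> 1       demo        5       D              Q              K              b 10
#> 2       demo        9       D              A              T              y  4
#> 3       demo       15       E              V              M           none  0
#> 4       demo       32       N              P              S              y 12
#>   sigma score
#> 1  2.17  4.60
#> 2  2.17  1.84
#> 3  2.17  0.00
#> 4  2.17  5.52
```

Each row is one cleavage site: the winning fragment series, its matched
intensity `u`, the spectrum's background standard deviation `sigma`, and
the signal score `u / sigma` — the site's fragmentation efficiency. Site
15 matched no peak (score 0); site 32 is an N-P site, the motif with the
strongest expected enhancement.

A full study — generate a 36-protein cohort with structures and spectra,
then run everything:

```r
study <- generate_study("study_dir", seed = 1)
res <- run_pipeline(default_config(protein_table = study$table_path))
print(res)
#> PSD fragmentation-efficiency analysis
#>   proteins: 36 (3 excluded by pLDDT filter)
#>   cleavage sites: 617 (509 with matched signal)
#>   score > 10: D 61.8%, E 14.7%, N 12.3%
#>   E/N eCDF Pearson r: 0.991
#>   ...
```

`res$records` holds the per-site table (scores joined with all
properties), `res$regression` the per-class NB coefficient tables with
standard errors, Wald p-values and the LRT p, `res$categorical` and
`res$pairwise` the Kruskal–Wallis and Mann–Whitney results, and
`res$ecdf_summary` the tail fractions and E/N eCDF correlation. With
`outdir` set, all tables are written as TSV plus a run log of filter
counts and parameters.

Real data plug in the same way: a TSV protein table with `protein_id`,
`sequence`, `spectrum_path` (two-column ASCII centroided peak list),
`structure_path` (PDB with pLDDT in the B-factor column) and
`precursor_mz`.

A thin command-line wrapper with subcommands (`simulate`,
`predict-fragments`, `score`, `extract-props`, `rin`, `run-all`) is
installed at `inst/scripts/psdfrag`.

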