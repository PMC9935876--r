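# fatdachs

Quantitative analysis of heterophilic cadherin complexes of the
Fat–Dachsous family. Fat4 and Dchs1 are atypical cadherins whose
extracellular cadherin (EC) repeats interdigitate to form the
planar-cell-polarity signalling complex; characterising such a complex
means measuring the same handful of quantities over and over: how much
surface is buried and between which EC domains, which residues form
interchain hydrogen bonds and salt bridges, how terminal domains tilt
between crystal forms, how conserved the interface is across orthologs,
how tightly the fragments bind in solution, and whether the two proteins
co-accumulate at cell–cell borders in co-culture. This package implements
each of those measurements as a small, separately testable tool, plus
seed-deterministic synthetic generators that plant known ground truth for
every stage.

## What's in the box

* **Structure model** — `read_structure()` / `write_structure()` parse
  PDB files into a flat atom table (first model, highest-occupancy
  altlocs, heavy atoms, calciums retained); `assign_domains()` labels EC
  domains from explicit residue ranges, linkers included.
* **Surface burial** — `compute_sasa()` is Shrake–Rupley SASA on a
  deterministic Fibonacci lattice (probe 1.4 Å, 960 points by default,
  Rcpp core); `interface_area()` reports
  ½[ΔSASA(A) + ΔSASA(B)] and `domain_pair_areas()` attributes burial to
  EC-domain pairs by nearest opposing atom, so pair areas sum exactly to
  the total.
* **Contacts** — `find_hydrogen_bonds()` (heavy-atom N/O donors and
  acceptors, ≤3.5 Å) and `find_salt_bridges()` (basic N vs acidic O,
  ≤4.0 Å, one per residue pair), disjoint by construction;
  `contact_cutoff_sensitivity()` sweeps the cutoffs;
  `interface_report()` bundles everything.
* **Superposition geometry** — `kabsch_superpose()` (SVD,
  proper rotation enforced), `domain_axis()` (terminal-thirds Cα
  centroids) and `ec1_tilt_angle()` (EC1 axis angle after EC2–EC3
  alignment) for interdomain hinge measurements.
* **Conservation and motifs** — `column_conservation()` (normalised
  Shannon entropy or BLOSUM62 sum-of-pairs, nine conservation grades),
  `paint_interface()` to map scores onto residues, and `scan_fj_motif()`
  for the Four-jointed kinase recognition motif D-X-N-D-X₇-S/T.
* **ITC** — `simulate_thermogram()` and `fit_one_site()` implement the
  one-set-of-sites Wiseman isotherm with displaced-volume corrections;
  the fit is a classed model object with `print`/`summary`/`coef`/
  `predict`/`residuals`/`plot`/`simulate` methods; `fold_reduction()`
  compares mutant to wild-type affinity.
* **Border colocalization** — `border_accumulation()` and
  `border_complexes()` score fluorescence at annotated cell boundaries
  (Euclidean-disc edge masks, length-normalised, Gaussian-blurred
  two-channel product); `compare_groups()` runs the group t test.
* **Synthetic data** — `make_toy_complex()`, `make_msa()`,
  `make_cell_image()` and `write_fixture_suite()` generate fixtures with
  planted, exactly known ground truth.
* **Pipeline** — `run_pipeline()` chains the stages from a list or YAML
  config with echoed parameters, input checksums and per-stage
  artifacts; `inst/scripts/fatdachs-cli.R` is the command-line front
  end.

See the methods vignette (`vignettes/fatdachs-methods.Rmd`) for the
models, parameter rationale and the scope of the synthetic validation.

## Worked example

Build a toy two-chain complex with three planted interchain contacts,
inventory its interface, and fit a simulated titration back to its
generating affinity:

```r
library(fatdachs)

## A two-chain toy complex with planted interchain contacts
toy <- make_toy_complex(
  planted_contacts = list(
    list(domain_A = "EC1", domain_B = "EC2", kind = "hbond",       distance = 3.0),
    list(domain_A = "EC3", domain_B = "EC4", kind = "hbond",       distance = 3.2),
    list(domain_A = "EC2", domain_B = "EC3", kind = "salt_bridge", distance = 3.4)),
  seed = 2L)

rep_ <- interface_report(toy$structure, "A", "B")
rep_
#> Interface A:B — 2 hydrogen bonds (<= 3.5 A), 1 salt bridges (<= 4.0 A)

rep_$contacts[, c("kind", "resid_A", "resno_A", "elety_A",
                  "resid_B", "resno_B", "elety_B", "distance")]
#>          kind resid_A resno_A elety_A resid_B resno_B elety_B distance
#> 1       hbond     ALA      12       N     ALA      36       O      3.0
#> 2       hbond     ALA      60       N     ALA      84       O      3.2
#> 3 salt_bridge     LYS      37      NZ     ASP      61     OD1      3.4

## Buried surface at the interface (PISA half-convention)
ia <- interface_area(toy$structure, "A", "B")
ia$interface_area
#> [1] 73.84932

## Fit a simulated one-set-of-sites titration (true Kd = 2 uM)
truth <- itc_params(n = 1, K = 1 / 2e-6, delta_H = -12000)
tg  <- simulate_thermogram(truth, noise_sd = 0.1, seed = 1L)
fit <- fit_one_site(tg)
fit
#> One-set-of-sites ITC fit (19 injections used)
#>   n      = 1.008
#>   Kd     = 2.26 uM
#>   dH     = -1.23e+04 cal/mol
#>   offset = 181 cal/mol
```

The planted contacts are recovered exactly — same residues, atoms and
distances — and the 2 µM titration simulated at 0.1 µcal noise fits back
to 2.26 µM.

## License

MIT (see `LICENSE`).
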