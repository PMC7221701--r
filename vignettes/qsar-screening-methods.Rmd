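---
title: "Models and methods behind the qsarfunnel screening workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the qsarfunnel screening workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarfunnel)
```

# Scope

`qsarfunnel` implements a ligand-based modeling and multitarget
virtual-screening workflow for small-molecule inhibitors: activity data
are curated into log10(IC50) responses (IC50 in nM), molecular descriptors
are computed from structure (or ingested when they require quantum
chemistry), linear models are built by best multilinear regression (BMLR)
and nonlinear models by a stepwise backpropagation network builder
(BeANN), both are validated by cross-validation and randomization, and
the resulting models refine a docking-based screening funnel through
ligand-efficiency, drug-likeness, solubility and applicability-domain
filters down to a multitarget candidate list.

Docking itself, conformer generation, semi-empirical quantum chemistry
(AM1) and solubility prediction are deliberately outside the package:
their outputs — score tables, 3D coordinates, AM1 descriptor columns,
solubility categories — are consumed as inputs.

# Molecular graphs and descriptors

Molecules are attributed graphs built from SMILES (`parse_smiles()`,
hand-written so atom order, implicit-hydrogen bookkeeping and positional
parse errors are fully specified) or from V2000 SDF via ChemmineR
(`read_sdf()`), which also attaches 3D coordinates. Stereochemistry is
parsed and ignored: every descriptor here is stereo-insensitive.

Two graph conventions coexist, following the CODESSA lineage:

* **hydrogen-suppressed** for topological descriptors — the Balaban
  distance-connectivity index `J` and the Kier shape indices
  `kappa1..3` built from path counts;
* **hydrogen-filled** for constitutional and information-content
  descriptors — atom/bond/element counts, average atomic weight, and the
  Shannon-entropy indices IC/SIC/BIC/CIC of order 0–2 over atom
  equivalence classes (BIC augments the neighbor signature with bond
  orders; aromatic bonds count 1.5).

A consequence worth noting: isomers that differ in hydrogen count (e.g.
ethane vs ethene) have different hydrogen-filled composition fractions
and therefore different IC0; only equal-composition isomers such as
1-butene vs cyclobutane share IC0 while differing in the bonding variant.

Empirical partial charges use one-shot Sanderson electronegativity
equalization (`zefirov_charges()`): the molecular electronegativity is
the geometric mean of atomic Sanderson values and
`q_i = (S_mol − S_i) / (2.08 sqrt(S_i))`, shifted uniformly onto the net
formal charge. The scheme is deliberately non-iterative; it provides the
charge-related descriptor family (extrema, HACA) without any quantum
chemistry.

Surface areas come from a Shrake–Rupley sampler with a deterministic
golden-spiral lattice (default 960 points per atom, probe 1.4 Å, Bondi
radii), so SASA values are exactly reproducible. The CPSA family
(PPSA1/2, HASA, FHASA, HACA-1/-2, HDCA-1/-2) combines those areas with
partial charges; the "-2" variants normalize by `sqrt(TMSA)`. The exact
CPSA variant formulas are not uniquely fixed in the literature, so the
definitions used here are written out in `?cpsa_descriptors` and the
models built on them are self-consistent. Donor hydrogens must be
explicit atoms with coordinates (hydrogen-filled SDF input); acceptors
are N and O, halogens excluded. Descriptors that are undefined for a
structure (kappa3 with no 3-bond path, an element-filtered extremum with
no matching atom) are stored as `NA`, never imputed as zero — model
building is restricted to complete columns, because silent zero
imputation would distort the regressions.

AM1-type quantum descriptors (LUMO energy, heats of formation, bond
resonance/repulsion terms, average valency, ...) are **never** computed
internally; `attach_external_descriptors()` joins them from a CSV keyed
by compound id and tags their provenance `external`. Models that need an
absent external column fail loudly.

# Best multilinear regression

The response throughout is `log10(IC50 [nM])`. `curate_dataset()`
applies the curation rules typical for such sets: positive IC50 only,
molecular weight below 600 Da when available, exclusion of gross
activity outliers (|z| > 3 on the log scale — the chosen operational
reading of "discard strong/strange deviations", configurable), and a
warning when the activity span is under 3 log units.

`fit_ols()` is QR-based least squares with the full statistics block
(R², s² = SSres/(N−k−1), Fisher F, coefficient standard errors and
t-values). The BMLR search (`bmlr_search()`) is a breadth-limited
forward selection: all descriptor pairs whose mutual |r| does not exceed
the collinearity cap (default 0.8) are fitted, the best `breadth`
(default 50) kept, and each retained subset is extended one descriptor
at a time, re-ranked by R² (ties: F, then name order) and pruned again,
up to `max_terms`. The original BMLR's exact breadth and collinearity
parameters are not published, so they are exposed as configuration with
these defaults; with unbounded breadth the search provably coincides
with exhaustive best-subset for small pools, which is how it is tested.
In-sample R² of the best model is non-decreasing in model size by
construction.

Validation:

* **Leave-one-out** (`loo_r2cv()`) via the hat-matrix identity
  `e_(i) = e_i / (1 − h_ii)`; mathematically identical to N explicit
  refits (and tested against them), so the choice is purely
  computational.
* **ABC cross-validation** (`abc_split()`, `abc_validate()`): data
  sorted ascending by y are dealt into three interleaved subsets
  (positions 1,4,7,… → A; 2,5,8,… → B; 3,6,9,… → C); the model is
  refitted on each pairwise union with the same descriptors and scored
  on the held-out third; `R2_abc` is the mean of the three external R²
  values. External and CV R² are squared Pearson correlations between
  observed and predicted.
* **Scrambling** (`scramble_validate()`): y-, x- or xy-permutation
  followed by a refit, seeded and reproducible. The full protocol uses
  10,000 trials; the test suite and examples run 200–500, which is
  ample to locate the null mean (≈ k/(N−1) for independent data). The
  x mode permutes each descriptor column independently — permuting all
  columns jointly would merely relabel rows and reproduce the y-mode
  distribution.

# The neural-network builder

The nonlinear model is a multilayer perceptron (`n-h1[-h2]-1`) with tanh
activation in every non-input layer, trained by per-pattern
backpropagation with momentum (generalized delta rule; learning rate 0.1
or 0.2, momentum 0.02, at most 700 epochs). Inputs and target are
affinely normalized into (−1, 1) with bounds taken from the training
subset only. Because the output neuron is tanh, mapping the training
extremes exactly onto ±1 puts them at the saturation limit; the
`margin` parameter (default 1.0, i.e. the exact mapping) can be set
below 1 to keep targets strictly interior, and the XOR example in the
test suite uses 0.9 for that reason.

The validation set is every 5th point of the y-sorted data (sorted
positions 5, 10, 15, …), giving floor(N/5) validation points — the rule
reproduces all four published train/validation splits exercised in the
tests (239→192/47, 378→303/75, 229→184/45, 213→171/42). Validation data
never contribute gradient updates; they drive early stopping: training
halts when the validation RMS has exceeded its running best for
`patience` consecutive epochs (default 20 — the stopping rule is stated
qualitatively in the source protocol, so the patience form and default
are this package's choice), and the best-epoch weights are restored.

Initial weights are drawn uniformly from (−1, 1); of 20 candidate draws
the set with overall mean closest to zero is used. Pattern order within
an epoch is a seeded shuffle (sequential updating is prescribed, the
order is not; a fixed seeded shuffle makes runs reproducible). Bias
units are present in every non-input layer. The inner training loop is
compiled (Rcpp) for speed; its analytic gradient is verified against
central finite differences of the R-side forward pass.

`beann_select()` grows the input set stepwise: the best 1-input network
by `R2_sum = R2_tr + R2_val` is found over a candidate pool (union of
the top-15 descriptors by |Pearson r| with y and the BMLR descriptors,
`candidate_pool()`); holding chosen inputs fixed, every remaining
descriptor is tried as the next input. Each candidate trains on the same
split from the same seed policy, so selection is deterministic; selected
input sets are nested across sizes by construction.

# The screening funnel

`run_screen()` applies conjunctive filters per compound, retaining a
full pass/fail ledger for every compound including excluded ones:

1. **Energy/efficiency**: exclude if ΔG > −8.0 kcal/mol or
   LE < 0.35, with LE = |ΔG| / heavy-atom count. The inequalities are
   strict, so boundary values are kept. The LE definition is the one
   that reproduces the published reference-inhibitor values (e.g.
   donepezil −10.2 kcal/mol over 28 heavy atoms → 0.36) after
   half-up rounding to two decimals; full precision is kept internally
   and `round_half_up()` rounds in decimal semantics.
2. **Lipinski ≥ 3/4**: violations counted over MW > 500 Da, logP > 5,
   HBD > 5, HBA > 10, with HBA = N+O count (the original
   exclusion-list variant is not used; the reading is documented here).
   logP is an ingested property — the package does not predict it.
3. **Solubility**: exclude the `low` category (< 0.01 mg/mL; moderate
   0.01–0.06; high > 0.06). Categories are inputs, derivable from a
   mg/mL column.
4. **Multitarget efficiency**: LE ≥ 0.4 (inclusive) for *every*
   requested target; the subset satisfying all four Lipinski conditions
   is reported separately.
5. **Applicability domain**: per-descriptor training min–max box
   widened by 20% of the range *on each side* (the published "+20%"
   augmentation; widening per side is this package's documented reading
   of it). One out-of-range descriptor discards the prediction.
6. **Consensus**: for in-domain survivors, the arithmetic mean of the
   linear and network predictions of log10(IC50).

Because the filters are conjunctive, the selected set is invariant
under any permutation of filter order; the implementation fixes an
order only for ledger readability. Binding-mode inspection and
MD-based confirmation are human steps; the report flags candidates
rather than automating them.

# Synthetic data and what the tests show

The generators in `gen_linear_dataset()`, `gen_nonlinear_dataset()`,
`gen_null_dataset()`, `gen_docking_table()` and `gen_molecule_set()`
are pure functions of a specification plus seed. Defaults are fixed at
realistic study scale — n = 239 compounds, 3 informative among 20
descriptors, coefficients (0.6, −0.5, 0.45), noise σ = 0.3 log units —
which lands fitted R² in the high-0.8/low-0.9 band a good multilinear
QSAR model shows, and y spans at least 3 log units as curated activity
sets should. The nonlinear surface is a sum of two saturating tanh
terms (n = 250, σ = 0.2): a single-descriptor linear probe explains
under 0.6 R² while a 4-4-1 network reaches validation R² above 0.8.
The docking generator places every compound's energies and properties
constructively so that stage survivor counts match a requested vector
exactly, and ships the intended ledger so the funnel can be verified
against construction.

What the synthetic data do *not* emulate: correlated descriptor blocks
of real descriptor pools (available via `rho` but off by default),
heteroscedastic or laboratory-structured assay noise, activity cliffs,
and any real chemistry in the descriptor–activity link. Passing tests
therefore demonstrate correctness of the machinery under its stated
model, not predictive validity on experimental sets; the published
headline statistics of the original training sets cannot be reproduced
without their curated activities and AM1 descriptor values, which are
not distributed.

Problem sizes throughout the suite (100-replicate recovery at n = 200,
500 scrambling trials, 960-point SASA lattices) are the package's
chosen desk-scale defaults: large enough that every statistical claim
is tested at meaningful power, small enough to run anywhere.

# Numerical choices and limitations

* OLS uses column-pivoted QR; singular designs raise an error naming
  the collinear columns rather than silently dropping them.
* Ranking ties in the BMLR search break by F, then by sorted descriptor
  names — fully deterministic for a fixed pool order.
* `round_half_up()` carries a 1e-9 guard so values such as 9.1/20,
  whose binary representation sits infinitesimally below 0.455, round
  like their decimal selves.
* The SMILES dialect covers the organic subset, brackets, charges,
  ring closures and aromatic perception adequate for screening
  libraries; it does not kekulize, and exotic valences outside the
  allowed-valence table are rejected rather than guessed.
* Implicit hydrogens on aromatic atoms follow the trivalent-carbon
  convention; aromatic nitrogen without a bracket H is treated as
  pyridine-like.
* 2-2-1 XOR training has well-known symmetric local minima; with some
  seeds backpropagation stalls there. This is a property of the
  architecture, not a defect; the deterministic seed policy makes any
  such outcome reproducible.
* The z-based outlier rule and the per-side AD expansion are documented
  operational readings of qualitative prescriptions; both are
  configurable where a different reading is preferred.
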