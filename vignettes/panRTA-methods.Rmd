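---
title: "panRTA: model, fitting and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panRTA: model, fitting and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panRTA)
```

## The prediction model

Class II MHC molecules bind peptides in a groove open at both ends, so only
a 9-residue core of a longer peptide (typically 15-25 residues) interacts
substantially with the protein. A peptide of length $L$ admits $L-8$
placements of that core — the binding registers $M = 0, \dots, L-9$. panRTA
scores a peptide against an allotype $T$ in two steps.

**Register energy.** The affinity of the core starting at offset $M$ is a
sum over the nine core positions of contributions that couple the peptide
residue type at each position to the MHC residues it contacts:

$$\Delta G_M \;=\; \sum_{i=1}^{9}\sum_{j=1}^{20}\sum_{l=0}^{N_g(i)}
\beta_{ijl}\, x_{i+M,j}\, z_{i,T,l},$$

where $x$ is the one-hot encoding of the peptide (columns in fixed
alphabetical order of the one-letter codes), $z_{i,T,l}$ indicates whether
allotype $T$ carries residue variant group $l$ at core position $P_i$, and
$\beta_{ijl}$ (kcal/mol) is the fitted contribution of peptide residue $j$
at $P_i$ contacting group $l$. Group $l = 0$ collects the contacting MHC
residues invariant across the training panel, so its slice of $\beta$
plays the role of a per-allotype-independent profile; the remaining groups
encode allele-specific variation.

**Thermodynamic average.** The predicted affinity is the Boltzmann-weighted
average over registers,

$$\Delta G \;=\;
\frac{\sum_M \Delta G_M \, e^{\Delta G_M / kT}}
     {\sum_M e^{\Delta G_M / kT}},$$

computed after subtracting $\max_M \Delta G_M$ from all register energies
so the exponentials never overflow. Affinities are on a scale where larger
values mean stronger binding ($\Delta G = -RT\,\ln(\mathrm{IC}_{50}
\text{ in M})$), which is what makes the $e^{+\Delta G/kT}$ weighting
concentrate on strongly binding registers. In the limits, the average
approaches the best register as $kT \to 0$ and the arithmetic mean as
$kT \to \infty$; it always lies between the extreme register energies, and
adding a constant to every register shifts it by exactly that constant.

### Residue variant groups

The unit of allotype encoding is the *residue variant group*: a maximal set
of (MHC residue number, residue type) variants at residues contacting a
given core position that always co-occur across the training panel. Two
variants share a group exactly when the sets of panel allotypes carrying
them are identical; variants carried by every panel member form the
invariant group $l = 0$. Splitting such co-occurring variants into separate
parameters would add directions the training data cannot determine, so the
grouping is the most concise identifiable description of the panel's
variation.

Contacting residues are extracted from peptide-MHC complex structures by a
strict rule: any non-hydrogen atom pair closer than 4.0 Å, unioned over
structures, with residue numbers mapped onto the panel alignment. A contact
map can equally be supplied as a table, decoupling catalog construction from
structures. Alignment gaps at contact positions are treated as a distinct
variant type `-`, so deletions split groups rather than being silently
ignored.

Profiling a new allotype sets $z_{i,l} = 1$ only when *every* variant of the
group is present. Variants the catalog has never seen contribute zero energy
(their parameters do not exist); they are reported together with two
coverage fractions — group-level (matched groups over matched groups plus
unmatched variants, the default) and residue-level (covered contacting
variant residues over all such residues) — so low-coverage predictions can
be flagged rather than silently trusted.

## Fitting

Parameters are estimated by minimizing the mean square error between
predicted and experimental affinities subject to an L1 constraint
$\sum_{ijl} |\beta_{ijl}| \le t$. The constraint performs model selection:
as $t$ shrinks, parameters hit exactly zero, which both regularizes the
large parameter space and keeps the model interpretable.

The objective is smooth but nonconvex (registers compete through the
Boltzmann average), so the solver is a seeded multistart of local solves:

* each $\beta_{ijl}$ is split as $\beta^+ - \beta^-$ with
  $\beta^\pm \ge 0$ and the single linear constraint
  $\sum (\beta^+ + \beta^-) \le t$;
* each start runs a spectral projected gradient descent (Barzilai-Borwein
  step lengths, nonmonotone Armijo line search) with analytic gradients of
  the full model chain; the projection onto
  $\{u \ge 0, \sum u \le t\}$ is the exact simplex-threshold projection,
  so iterates are always feasible;
* convergence is declared when the projected gradient infinity norm falls
  below `gtol` ($10^{-6}$ by default) within `maxit` (2000) iterations;
* starts are uniform in $[-0.5, 0.5]$ kcal/mol (plus one zero start); when
  a grid of bounds is supplied, each start draws its own $t$; the default
  number of starts is 20;
* parameters whose design column is empty — groups carried by no training
  record — are pinned to zero, the same convention used when predicting
  allotypes with unrepresented groups.

**SVD initializer.** A good starting point comes from combining
single-allotype fits: for fixed $(i,j)$, one seeks group parameters whose
membership-weighted sums best reproduce the per-allotype coefficients
$(\beta_a)_{ij}$ across the panel. This is a least-squares problem
$\min_b |Zb - c|$ solved through the singular value decomposition of the
membership matrix $Z$, zeroing singular values below $\varepsilon$
(default $10^{-8}$ times the largest singular value, since no principled
scale is available a priori); on rank-deficient $Z$ this returns the
minimum-norm solution. The initializer is exact (zero residual) whenever
the single-allotype coefficients are actually generated by a pan-allotype
model whose memberships span them.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `kT` | 0.592 | kcal/mol | register weighting temperature (RT at 298 K); stored inside each model because predictions depend on it |
| `l1Bound` ($t$) | per fit | kcal/mol | L1 budget; the central regularization dial |
| `RT` | 0.592 | kcal/mol | IC50 conversion constant |
| `epsilon` | $10^{-8}\sigma_{\max}$ | — | pseudoinverse cutoff of the initializer |
| `multistart` | 20 | — | local solves per fit |
| `gtol`, `maxit` | $10^{-6}$, 2000 | — | solver stopping rules |
| `binderIC50` | 1000 | nM | binder cutoff for AUC labels |

No temperature or IC50 convention is canonical in the binding literature;
both conversions here use $RT = 0.592$ kcal/mol and are exposed as
arguments, and every evaluation report records the binder cutoff it used.
The register index $M$ is 0-based with the core occupying peptide positions
$M+1,\dots,M+9$; ties in core ranking resolve to the smaller $M$
(N-terminal register). Non-canonical residues (B, J, O, U, X, Z) are
rejected with the offending position named.

## Evaluation statistics

* **AUC** is the Mann-Whitney statistic normalized by the number of
  binder/non-binder pairs; midranks count tied scores as 1/2, making the
  value invariant under any strictly monotone transform of the scores.
* **RMSE / Pearson correlation / mean signed difference** are computed
  directly; the signed difference diagnoses systematic affinity shifts that
  inflate RMSE without harming discrimination. Spearman correlation is
  available as an option.
* **Exact Wilcoxon signed-rank test**: zero differences dropped, midranks
  on the absolute differences, and the exact null distribution of the
  positive-rank sum built by convolution over sign assignments — equivalent
  to enumerating all $2^n$ assignments and valid with ties, where the
  textbook exact test is not. One-sided (`greater`) is the default; the
  two-sided value doubles the smaller tail, capped at 1. $n \le 25$ keeps
  the enumeration regime explicit.
* **Leave-one-allele-out cross-validation** refits the model once per
  held-out allotype, records a per-fold training manifest so the protocol
  is auditable, warns when the held-out allotype carries groups no training
  allotype has, and scores predictions with the statistics above.
* **Specificity variation**: the contribution matrix
  $\Delta G_{T,i,j} = \sum_l \beta_{ijl} z_{i,T,l}$ is summarized per
  position by its population standard deviation over the 20 residue types
  ($1/20$ normalization); positions with large $\sigma_{T,i}$ behave as
  anchor positions. The max-minus-min range is reported as a secondary
  statistic. $\sigma$ is invariant under adding a constant to all 20
  contributions at a position.

## The synthetic study design

Because the published training compilations are external, the package
validates its pipeline on synthetic data whose generative process is
*exactly* the model the fitting assumes — which is the point: failures then
indicate defects in the machinery, not model misspecification.

`syntheticSpec()` fixes the study conditions; the defaults describe one
emulated panel and are not tuned per experiment:

* five allotypes (the size of a small class II training panel), with one
  polymorphic group at the P1- and P8-like positions and two elsewhere,
  mirroring the observation that P1 variation in HLA-DR reduces to a single
  dimorphism while most other positions vary more;
* groups are single-residue variants forming a mutually exclusive family
  per position, each allotype carrying exactly one — the same structure
  profiling produces from real mutually exclusive sequence variants;
  membership is random with every group carried by at least one allotype
  (`minGroupCount = 2` additionally guarantees any single hold-out leaves
  all groups represented, the precondition of a transfer experiment);
* ground-truth $\beta^*$ is sparse (25% nonzero) with entries uniform in
  $\pm 2$ kcal/mol, giving register energies spread over a few kcal/mol —
  comparable to the 4-5 orders of magnitude of IC50 spread in competition
  assay compilations;
* peptides are uniform random 15-25-mers over the 20 residue types (no
  background composition), affinities are the model's Boltzmann averages
  plus Gaussian noise of 0.5 kcal/mol ($\approx$ 0.4 log10 IC50 units,
  typical assay reproducibility), and allotypes are assigned round-robin.

All generators are pure functions of the spec, including its seed.

What the synthetic data deliberately do **not** emulate: assay
heterogeneity and censored IC50 values, peptide length and flanking-residue
effects (the model has no such terms), amino-acid background frequencies,
and real linkage between MHC positions. Passing synthetic tests therefore
demonstrates the correctness of encoding, fitting, transfer and scoring —
not that the model assumptions hold for laboratory data.

A miniature PDB fixture with atoms planted at scripted distances (3.5 Å
contact, exactly 4.0 Å non-contact, a hydrogen at 1.0 Å whose heavy atoms
sit at 4.5 Å) exercises the contact rule's strict inequality and
heavy-atom filter by construction.

### Problem sizes used in the shipped tests

The test suite and the acceptance script run, among smaller cases: a
transfer experiment with 4 allotypes × 1000 records at noise 0.5 kcal/mol
(held-out fold only), an identifiability run with 2000 records at noise
0.25, noiseless recovery and least-squares-equivalence fits on 500
single-register records, and the exact benchmark-table statistics. These
sizes were chosen as the smallest at which the corresponding properties are
cleanly identifiable.

## Numerical choices and edge cases

* Register averaging always max-shifts before exponentiation; weights are
  renormalized to sum to 1.
* The design matrix is sparse 0/1 (rows = registers of all records); all
  objective and gradient evaluations are sparse matrix-vector products, so
  fits with a few thousand records run in seconds to minutes.
* `t = 0` returns the exact zero model without iterating.
* Solver line search halts at step $2^{-40}$; a fit where no start reaches
  `gtol` returns the best iterate with a warning and the full start log.
* Tiny fitted values (below $10^{-12}$) are truncated to exactly zero
  before counting nonzero parameters.
* Model JSON serialization stores nonzero entries only and embeds the
  catalog plus a content fingerprint; restored models reproduce
  predictions to full double precision (~1 ulp).

## Known limitations

* No global-optimality guarantee: the objective is nonconvex and multistart
  local descent can return a suboptimal basin; the start log makes this
  visible.
* Allotypes with variants outside the catalog receive zero contribution for
  them; accuracy degrades in proportion to missing coverage, and only the
  coverage report signals it.
* Peptide flanking residues and length effects are out of model scope.
* The published per-allotype benchmark AUCs cannot be regenerated without
  the external training compilations; the package instead reproduces the
  statistics over the printed tables and validates the machinery
  synthetically. The conserved-CLIP-register analysis likewise requires the
  externally published fitted parameter tables; an importer
  (`importPublishedParameters()`) is provided, and the corresponding check
  in the test suite remains unsatisfied until those tables are dropped into
  `inst/extdata/published/`.
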