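---
title: "Edgotype classification and the Bayesian fitness-effect model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edgotype classification and the Bayesian fitness-effect model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgotype)
```

# The question and the model

A missense mutation can leave a protein's interactions untouched
(quasi-wild-type, QW), remove specific interactions by damaging one
binding interface (edgetic, E), or remove all interactions by
destabilising the fold (quasi-null, QN). The package estimates how each
of these perturbation patterns maps onto organismal fitness: the
probability that a mutation of edgotype T is effectively neutral (N),
mildly deleterious (M), or strongly detrimental (S).

Two phenotype-labelled mutation sets anchor the inference. Common
non-pathogenic variants (minor allele frequency at least 1%) are treated
as effectively neutral, so their edgotype fractions estimate P(T|N);
Mendelian pathogenic mutations are treated as mildly deleterious on
average, giving P(T|M). Strongly detrimental mutations never appear in
either set — they are eliminated too quickly — so their edgotype
distribution P(T|S) is a modelling choice, bracketed by two extremes:

* **Assumption I**: strongly detrimental mutations are all quasi-null
  (P(QN|S) = 1). This is the biologically preferred reading: total loss
  of a protein is the most radical perturbation.
* **Assumption II**: they are distributed like mildly deleterious
  mutations (P(T|S) = P(T|M)), the least destructive scenario.

With genome-wide priors for new missense mutations,
P(N) = 0.27, P(M) = 0.53, P(S) = 0.20 (`fitnessPriors()`), the chain is

$$P(T) = P(T|N)P(N) + P(T|M)P(M) + P(T|S)P(S),$$
$$P(X|T) = \frac{P(T|X)P(X)}{P(T)}, \quad X \in \{N, M, S\}.$$

`fitnessPosterior()` evaluates this exactly; no sampling is involved.
Because the truth lies between the assumptions, `mergeAssumptions()`
reports, per (edgotype, fitness class), the interval from the
Assumption-I estimate to the mean of the two estimates — deliberately
asymmetric, reflecting that Assumption I is considered the better
approximation.

```{r}
ep <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
                    n = c(nonpathogenic = 1072, pathogenic = 318),
                    assumption = "I", dataset = "Y2H-SI")
fitnessPosterior(ep)
```

# Confidence intervals

Only P(T|N) and P(T|M) are estimated from data (binomial counts
$x_1/n_1$ and $x_2/n_2$); the priors and P(T|S) are fixed. Substituting
the marginal into the Bayes expression shows that every posterior is a
monotone transform of a combination of the two proportions, e.g.

$$\frac{1}{P(N|T)} = 1 + \frac{a\,P(T|M) + b}{P(T|N)},
\qquad a = \frac{P(M)}{P(N)},\; b = \frac{P(T|S)P(S)}{P(N)}.$$

`blandCi()` distinguishes two regimes:

* **Pure ratio** (the additive constant vanishes, or folds into a
  constant offset): the interval comes from the classical log-scale
  treatment of a ratio of two proportions, with
  $\mathrm{SE}(\log r) = \sqrt{(1/x_1 - 1/n_1) + (1/x_2 - 1/n_2)}$,
  transformed through the monotone expression. This covers Assumption I
  for QW and E, and — after algebra — every cell under Assumption II,
  because there P(T|S) is the *same estimate* as P(T|M) (perfect
  dependence, contributing no independent variance) and the combination
  collapses to a constant plus a multiple of one ratio.
* **Ratio with a free additive term** (Assumption I for quasi-null,
  where P(T|S) = 1 enters the numerator) and the sum form for
  P(S|T): a first-order delta-method interval on the transformed scale,
  propagating $p_i(1-p_i)/n_i$.

Numerical conventions: the 95% normal quantile is fixed at 1.959964 for
bit-reproducibility; a zero success count receives a continuity
correction of one half (with a warning); intervals are truncated to
[0, 1]. Published fractions may be supplied in place of counts, with an
explicit n — success counts are then fraction × n and may be
non-integer. The tests validate the analytic intervals against a
parametric bootstrap (10^6 binomial redraws, percentile interval; the
two agree to well under half a percentage point at the reference count
bases) and check empirical coverage (10^4 simulated count tables at the
Y2H-SI sizes give coverage within one point of nominal).

# Structure-based classification

**Interfaces.** Two residues are in contact when the minimum distance
over all heavy-atom pairs is at most the cutoff; a residue is
interfacial when it contacts any residue of the partner chain
(`interfaceResidues()`). The default cutoff is 5 Å, the standard contact
threshold; 4 and 6 Å are exercised by `cutoffSweep()` because the
downstream ratios P(E|N)/P(E|M) and P(QW|N)/P(QW|M) — the only data
quantities the QW and E posteriors depend on — should be stable against
this choice.

**Accessibility.** `residueSasa()` implements sphere-sampling
(Shrake–Rupley) accessible surface area over heavy atoms only: each atom
is inflated by the probe radius (1.4 Å, water-sized), 960 deterministic
golden-spiral points are placed on the inflated sphere, and the
accessible fraction excludes points inside any neighbouring inflated
sphere. 960 points keep the quadrature error under 2% (doubling the
count is a test invariant); an isolated atom reproduces
$4\pi(r + 1.4)^2$ exactly up to point discreteness. Van der Waals radii:
C 1.70, N 1.55, O 1.52, S/P 1.80 Å; unrecognised heavy elements fall
back to carbon. RSA divides ASA by a per-residue maximum; the shipped
default is the published theoretical max-ASA table (Tien et al. 2013),
chosen because it is reproducible from the literature, and any
user-supplied table (e.g. DSSP-derived percentiles) can be passed
instead. RSA is not clipped at 1.

**Location and edgotype.** Interface membership takes priority over RSA:
an interfacial residue is interfacial regardless of burial. Otherwise
RSA > 0.25 is exposed and RSA ≤ 0.25 (boundary included) is buried; 0.25
is the conventional interior/exterior segregation threshold. An
interfacial mutation is edgetic iff some partner's binding ΔΔG strictly
exceeds 0.5 kcal/mol — all partners above threshold are reported as
disrupted, matching the "disrupts at least one interaction" definition.
A buried mutation is quasi-null iff folding ΔΔG ≥ 2 kcal/mol
(inclusive). Interfacial mutations are never routed to the quasi-null
branch; consequently the quasi-null fractions, and through them the
quasi-null posteriors, are provably independent of the binding cutoff —
a structural robustness property the tests assert.

**Parsing conventions.** Only the first MODEL of a PDB file is read;
waters, hetero-compounds and hydrogens are dropped; residues are
renumbered sequentially per chain (1-based), which resolves insertion
codes — author numbering never reaches the position maps.

# Interactome assembly

Alignments are consumed from a tabular file (query, subject, E-value,
coordinate ranges, aligned strings); running the aligner is out of
scope. After filtering at E ≤ 10⁻⁵, one alignment is kept per
(protein, chain): smallest E-value, ties broken by more aligned pairs,
then lexicographic chain id. A PPI is annotated with a chain pair when
the chains share an interface and at least 50% of each chain's interface
residues map onto the corresponding protein. When several chain pairs
qualify, no published criterion exists; the package keeps the annotation
maximising min(coverage_a, coverage_b), then summed coverage, then
lexicographic template id — chosen to prefer templates that are good on
*both* sides and to stay deterministic. Template interface positions are
transferred to protein coordinates through the alignment map; unmapped
positions are dropped and counted. Homology-model coordinates are not
rebuilt: all downstream rules consume residue positions and template
geometry, so the template coordinates plus the position map preserve the
results while avoiding an external modelling tool.

In the pipeline, RSA for a protein is computed on its representative
chain *in isolation* (the partner chain excluded from the occluders):
the per-protein structural model is a monomer, and the partner's
influence is represented by interface membership, not by occlusion.

# Mutation mapping

The pathogenic filter keeps missense records labelled exactly
"pathogenic" (not "likely pathogenic", not compound labels), with at
least one review star and no conflicting interpretations. The common
filter keeps missense records that are validated, not withdrawn, carry
no pathogenic- or uncertain-type assertion (the enumerated, configurable
set: pathogenic, likely pathogenic, drug-response, uncertain
significance, other), and have MAF ≥ 1%; records with missing MAF are
dropped because commonness cannot be established. Flank verification
builds the window of up to 10 residues on each side of the site
(truncated at sequence ends) and requires the identical window, with the
wild-type residue at the site, at the reported position in *both* the
transcript translation and the protein sequence — the strictest reading,
chosen over allowing independent end-truncation per side, since the two
sequences should agree wherever both are defined. Duplicates at one
(protein, position) keep the first record in stable input order (a
highest-star policy is available behind a flag); common mutations
sharing a position with pathogenic ones are removed. Data-level
anomalies (positions beyond the sequence, unknown proteins) are reported
as per-record rejection reasons rather than aborting a run; malformed
schemas raise errors.

# The synthetic-data generator

The generator exists so that every stage is testable with known ground
truth and no downloads. It emulates the *statistical and geometric
structure* of the real inputs, not their biology:

* **Toy complexes** (`generateToyComplex()`): two heavy atoms per
  residue (a backbone-like CA and an offset CB) — enough for distance
  and accessibility computations without side-chain modelling.
  Designated interface pairs sit at 3.9 Å; every other cross-chain pair
  is beyond 6.5 Å, so interface recovery is unambiguous across the whole
  4–6 Å sweep. Non-interface residues fill compact cubic lattice blocks
  at 4.6 Å spacing, which yields a buried fraction (RSA ≤ 0.25) broadly
  comparable to globular proteins; the blocks are 12 Å apart.
* **Mutation tables**: ClinVar-like and dbSNP-like records with all
  filter fields, flanks built by the 10-residue rule, and a controlled
  fraction of records with one corrupted flank residue (ground truth
  recorded), so the verification rate is predictable up to binomial
  error.
* **Free-energy tables** (`generateDdgTable()`): class-conditional
  truncated Gaussians whose truncation bounds leave a margin around the
  classification thresholds — disruptive binding N(2.5, 1) truncated at
  0.6, benign binding N(0, 0.3) truncated above at 0.45, disruptive
  folding N(3.5, 1) truncated at 2.0, benign folding N(0, 0.3) truncated
  above at 0.45. The thresholds themselves are published; the generative
  families and margins are package choices made once so that ground
  truth is unambiguous.
* **Edgotype counts**: multinomial draws per phenotype class; the
  default class-conditional probabilities are the Y2H structural
  interactome fractions (97/1.5/1.5 and 74/13/13 percent).

Ground-truth quasi-wild-type mutations are placed preferentially on
exposed residues and may spill over to buried or interfacial positions
(with benign energy draws) — legitimate locations for quasi-wild-type
mutations — so the placement never fails on burial-heavy geometries.

What the generator does **not** emulate: realistic folds and side
chains, sequence evolution, correlated interfaces, realistic
allele-frequency spectra, or noisy free-energy predictions. Passing the
recovery tests therefore demonstrates that the pipeline's rules are
implemented exactly and compose correctly, not that the method would
achieve 100% accuracy on real structures — on real data the published
validation against experimental edgotypes is the relevant benchmark, and
the operations computing such comparisons (`evaluateAgainstExperiment()`)
are exercised on fixtures instead.

# Problem sizes and determinism

The default synthetic study uses 24 proteins (30–60 residues), 30 PPIs,
interface fraction 0.15, 300 non-pathogenic and 90 pathogenic mutations
(preserving the roughly 3.4:1 ratio of the reference mutation sets) and
a 5% flank-corruption rate — sizes at which the full pipeline, the
brute-force geometric oracles, the 10^6-draw bootstrap and the 10^4-table
coverage simulation all run comfortably on one core. Every stochastic
routine takes an explicit integer seed and derives per-complex
sub-streams from it; identical seeds give byte-identical output files,
and the pipeline itself is deterministic given its inputs (checksums are
recorded in the run summary).

# Known limitations

* The accessibility quadrature is a spherical-probe model; it does not
  reproduce DSSP's slicing algorithm exactly, so RSA values near the
  0.25 boundary can differ from DSSP-based analyses. The distance-cutoff
  sweep covers part of this sensitivity; a DSSP-compatible max-ASA table
  can be supplied.
* Gain-of-function (new-interface) mutations are out of scope; the
  edgotype vocabulary covers only disruption of pre-existing
  interactions.
* The experimental reference dataset's class sizes (47 and 197) are
  small; its intervals are wide, and its published fractions are
  consumed directly (non-integer implied counts) because the underlying
  integer counts are not published.
* Assumption II is treated as perfect dependence for variance purposes;
  a full Bayesian treatment with priors over the conditionals is out of
  scope.
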