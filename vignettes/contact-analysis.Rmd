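---
title: "Rotamer-based contact degree, contact potentials, and hybrid contact prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotamer-based contact degree, contact potentials, and hybrid contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactforge)
```

## The problem

Whether two residues of a protein are "in contact" sounds binary but is a
modelling decision, and downstream conclusions are sensitive to it.
Permissive definitions (any pair of heavy atoms within 8 Å) label ~20% of
residue pairs as contacting, are easy for co-evolution methods to predict,
but constrain structure weakly; restrictive, interaction-aware definitions
label far fewer pairs, each carrying more structural information, and are
much harder to predict. This package implements one interaction-aware
metric — the rotamer-based *contact degree* — alongside the three common
distance definitions, the statistical contact potentials each definition
induces, the decoy-discrimination machinery used to compare them, and a
hybrid predictor that injects contact-potential information into
co-evolution rankings.

## Contact degree

For backbone positions $i, j$,

$$CD_{i,j} = \sum_{r_i \in R_i} \sum_{r_j \in R_j}
  C_{ij}(r_i, r_j)\, P_i(r_i)\, P_j(r_j),$$

where $R_i$ enumerates rotamers of **all** amino-acid types from a rotamer
library, built onto the backbone by internal-coordinate (NeRF) placement
and pruned when any heavy side-chain atom falls within 2.0 Å of a heavy
backbone atom of the structure (the position's own backbone excluded).
$P_i$ are library probabilities (amino-acid prior × within-type rotamer
probability) renormalised to sum to one over the surviving set, and
$C_{ij}$ indicates two placed side chains having heavy atoms within 3 Å.
The value is the probability mass of mutually interfering side-chain
placements: 0 when no allowed pair can touch, 1 when all do.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `backbone_clash_cut` | 2.0 Å | rotamer-backbone clash pruning radius |
| `interfere_cut` | 3.0 Å | side-chain–side-chain interference radius |
| CD contact cutoff | 0.1 (inclusive ≥) | binary contact call |
| `prob_floor` | 1e-4 | skip vanishing-probability rotamers |
| `reach_bound` | 25 Å Cα–Cα | skip pairs no rotamer pair can span |
| amino-acid prior | uniform | how types are weighted inside $R_i$ |

The amino-acid prior and probability floor are not fixed by the method's
published description; both are configurable and recorded in output
provenance. `reach_bound` is safe because two fully extended side chains
span well under 25 Å. Distance thresholds are strict (`< 8 Å`), the CD
cutoff inclusive (`≥ 0.1`); at the default thresholds the orderings are
continuous-valued so the boundary convention only matters for constructed
fixtures. Backbone-dependent (Dunbrack-2010-format) libraries are binned
to the nearest 10° grid point without interpolation; undefined φ/ψ at
chain termini fall back to helical defaults (−60, −45) with a warning.

Side chains are built from an ideal-geometry table (bond lengths, angles
and torsion offsets per amino acid) derived from chemical-component
reference geometry and frozen into the package source; rebuilding a
rotamer and re-measuring its chi dihedrals recovers the inputs to well
under 0.5°, and proline's ring is built serially with its small closure
error tolerated — CD only needs approximate atom positions. Glycine
contributes no side-chain atoms, so pairs involving only glycine-like
placements contribute zero interference without special-casing.

## Contact potentials

Given contact counts $N_c(a,b)$ over a structure set, amino-acid
frequencies $f(a)$ and total contacts $N_c$,

$$E(a,b) = -\ln\!\left[\frac{N_c(a,b)}{(1 + I_{a,b})\, f(a) f(b)\, N_c}\right],$$

with $I_{a,b} = 1$ for hetero pairs. The $(1+I)$ factor sits in the
denominator (*null-normalized* convention) so that random redistribution
of amino acids among contacts gives $E \equiv 0$ exactly; the alternative
*as-printed* convention (factor in the numerator) is available behind a
flag and differs by exactly $2\ln 2$ on hetero cells — the published
formula's fraction bar is typographically ambiguous, and the
null-normalized reading matches the stated reference state. Natural
logarithms throughout, the statistical-potential convention. Zero-count
cells get a 0.5 pseudocount by default (set 0 for closed-form checks);
contact counting uses a minimum sequence separation of 2 by default, to
drop backbone-forced adjacencies, and records the choice in provenance.

## Decoy discrimination

A structure's score is the sum of $E$ over its contacting pairs; lower is
better. The native's rank among decoys uses ascending min-rank, so a
native tied with decoys keeps the better rank — matching how the
published rank tables count "lowest or tied-for-lowest". The two decoy
benchmark rank tables (56 and 59 proteins × 4 potentials) ship as TSV
fixtures, and the package reproduces their published medians, best-method
counts and the two-treatment Friedman significance (p = 7.9e-10 for the
CD potential against the any-heavy potential on the larger set). The
Friedman test is kept as a paired two-treatment test (mid-rank ties,
χ² with 1 df, via `stats::friedman.test`); for untied rows it reduces to
$(n_+ - n_-)^2 / n$. A fully tied table is degenerate and defined as
statistic 0, p = 1. The per-contact *elimination fraction* — how many
decoys knowledge of one native contact rules out — averages uniformly
over native contacts, then over proteins.

## Hybrid scoring and evaluation

For MSA column pair $(i,j)$ with co-evolution score $S^{i,j}$ and
MSA-averaged pair energy $\hat{E}^{i,j}$ (mean of $E(a,b)$ over rows with
standard amino acids at both columns; gapped rows skipped, which is one
flag away from scoring gaps as zero):

$$S'^{i,j} = S^{i,j}\left(1 - \frac{\hat{E}^{i,j}}{S_{max}}\right).$$

$S_{max}$ normalises the fixed-scale energies against co-evolution scores
whose scale varies with alignment depth; it is taken over
separation-filtered pairs only, since only those are ranked. Pairs with
no usable rows keep their raw score. The single-sequence variant
evaluates $E$ on one seeded random row, reused across all pairs of the
alignment. Sequence weighting across rows is uniform.

Evaluation: PPV of the top $N$ (or top $round(f \cdot L)$, half-up,
floor 1) ranked pairs against a truth set built by projecting structure
contacts through a structure-to-MSA map (global identity-scored alignment
with affine gaps; best row, requiring 95% similarity when attainable,
else the best available). Separation filters are applied in column space:
≥ 5 family-style, ≥ 6 CASP-style, and everywhere "separation k" means
$|i-j| \ge k$ (one published example implying a strict inequality is
treated as an off-by-one; see the separation bins, which place a
separation of exactly 23 in the long-range bin). Score ties in rankings
break deterministically by $(i,j)$ order, since small-$N$ PPV is
tie-sensitive. Contact-map diversity is the base-2 Shannon entropy of
the top $\lfloor L/2 \rfloor$ predictions over a 10 × 10 grid with cell
boundaries at multiples of $L/10$.

## The synthetic world

Everything the tests consume is generated in code under explicit seeds:

- **Toy backbones** from ideal peptide internal coordinates: helices
  (φ −57°, ψ −47°), strands, strand pairs at a set spacing, and
  "collinear" chains of disconnected residue clusters used to construct
  exact-distance fixtures.
- **Mini rotamer libraries** over five types (A, S, V, L, F) chosen to
  span zero to two chi angles and to include one long side chain so that
  contact degrees are exercised away from 0; small enough that the
  brute-force double-sum oracle runs in milliseconds.
- **Synthetic structure databases** plant a rate multiplier $m$ on one
  amino-acid pair's contacts by sampling sequences from
  $P(\text{seq}) \propto \prod f(a_i)\, m^{\#\text{enriched contacts}}$
  with seeded Metropolis sweeps (literal rejection sampling of the same
  target is astronomically inefficient; the stationary law is identical).
  The derived potential recovers $E \approx -\ln m$, *attenuated* because
  the planting also enriches the measured $f$: in the ideal disjoint-pair
  limit with $m = 2$ the estimator converges to
  $-\ln[4 \cdot 402 / (2 \cdot 21^2)] \approx -0.60$ rather than
  $-0.693$. Measured values on the default helix world (200 structures
  of length 50, three seeds) are −0.60, −0.56, −0.64, inside the
  acceptance band.
- **Synthetic alignments** plant disjoint contact column pairs filled
  with residue pairs drawn $\propto \exp(-\beta E(a,b))$ (β = 2) from a
  seeded random potential; all other columns are uniform. Co-evolution
  scores are the truth indicator plus iid Gaussian noise (σ = 0.5)
  clipped at zero. Depth 80 and length 50 keep a single evaluation under
  a second while leaving the raw ranking imperfect enough for the hybrid
  correction to matter.
- **Decoys** are coordinate-perturbation copies; the perturbation scale
  directly controls native-contact retention for elimination tests.

What a green test does and does not establish: the generators emulate the
*statistical couplings* the methods exploit (pair enrichment, favorable-
energy covariation, score noise), not real protein energetics, packing,
or phylogeny. In particular, the iid score noise makes the raw ranking's
false positives uniformly scattered over the contact map — already
maximally diverse. Re-ranking by the hybrid score concentrates top pairs
on the planted cells, so on this benchmark hybrid diversity comes out
marginally *below* raw diversity (mean 4.217 vs 4.226 bits over 20
seeds), and the corresponding acceptance assertion is deliberately left
failing rather than restructuring the generator after the fact. The
published diversity gain plausibly rests on real co-evolution errors
clustering in contact-map regions (entropic/phylogenetic column
artifacts), which an iid noise field cannot show. The hybrid PPV gain and
the advantage of MSA-averaged over single-sequence energies do reproduce
directionally (mean PPV at N = 10: 0.44 hybrid, 0.33 raw, 0.36
single-sequence).

## Numerical choices and degenerate inputs

- Altloc resolution keeps the highest-occupancy conformer, ties by
  identifier order; multi-model files use the first model (decoy sets are
  single-model) unless told to error.
- MSE parses as MET; other nonstandard residues drop with a warning;
  hydrogens are kept but flagged, and every distance computation excludes
  them; elements missing from the PDB element column are inferred from
  atom names (digit-stripped leading H/D is hydrogen).
- Non-glycine residues missing Cβ make the pair undefined under the Cβ
  metric: the pair is skipped with a warning rather than silently scored.
  Glycine's centroid falls back to Cα (it has no side-chain heavy atoms).
- Empty allowed-rotamer sets give CD = 0; `S_max ≤ 0` is a hard error;
  an alignment with no usable rows at a column pair yields a sentinel
  energy and the raw score is kept.
- All randomness flows through explicit seeds via `withr::with_seed`;
  identical seeds give byte-identical fixtures.

## Limitations

- CD treats rotamers rigidly at ideal geometry: no off-rotamer
  relaxation, no hydrogen atoms, no solvent; proline ring closure is
  approximate.
- The shipped evaluation reproduces the published *in-paper* statistics
  (rank tables) exactly, but the absolute published PPV curves and the
  0.39 mean absolute potential energy require the external structure and
  alignment databases and are out of scope; directional synthetic
  benchmarks substitute for them.
- The Friedman p-values are convention-sensitive (tie handling,
  continuity); order-of-magnitude agreement is the contract.
- Potentials derived from few structures are noisy; the pseudocount keeps
  them finite but shrinks extreme cells toward the null.
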