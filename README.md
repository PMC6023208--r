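# contactforge

Residue–residue contact analysis for protein structures: a rotamer-based
**contact degree** metric, classical distance-based contact definitions,
statistical contact potentials, decoy discrimination, and a hybrid
contact predictor that augments co-evolution scores with MSA-averaged
contact-potential energies.

The package is aimed at structural bioinformaticians who work on contact
prediction and structure scoring: it answers "which residue pairs of this
backbone *could* interact", "how informative is a given contact
definition", and "how much does an amino-acid pairing prior improve a
co-evolution contact ranking".

## The metrics

**Contact degree.** For backbone positions *i*, *j*:

```
CD_ij = Σ_{r_i ∈ R_i} Σ_{r_j ∈ R_j} C_ij(r_i, r_j) · P_i(r_i) · P_j(r_j)
```

where `R_i` is the set of rotamers (over all amino-acid types in the
library) that do not clash with the backbone (no heavy side-chain atom
within 2.0 Å of any heavy backbone atom other than the position's own),
`P_i` the library probabilities renormalised over the non-clashing set,
and `C_ij = 1` when any heavy side-chain atoms of the two placed rotamers
come within 3 Å. `CD_ij ∈ [0, 1]`; pairs with `CD ≥ 0.1` are called
contacts. CD is sequence-independent: it scores what the backbone
geometry *permits*, so it can be evaluated on backbone-only models.

**Distance definitions** (binary, strict `<`): any-heavy < 8 Å, Cβ < 8 Å
(Cα for glycine), side-chain centroid < 6 Å.

**Contact potential.** From contact counts over a structure set,

```
E(a, b) = −ln [ N_c(a,b) / ((1 + I_ab) f(a) f(b) N_c) ]
```

with `I_ab = 1` for `a ≠ b`, so that `E ≡ 0` under random redistribution
of amino acids among contacts.

**Hybrid score.** For MSA column pair (i, j) with co-evolution score
`S_ij` (DCA direct information or MetaPSICOV precision) and `Ê_ij` the
mean potential energy of the amino-acid pairs observed at those columns:

```
S'_ij = S_ij · (1 − Ê_ij / S_max)
```

**Contact-map diversity.** Shannon entropy (bits) of the top `L/2`
predictions over a 10 × 10 grid of the contact map,
`D = −Σ p_i log2 p_i ∈ [0, log2 100]`.

## Worked example

```r
library(contactforge)

## contact degree on a toy helix with a miniature rotamer library
st  <- make_toy_backbone("helix", 12, sequence = "AVLSF")
lib <- make_mini_rotlib(seed = 3)
compute_cd(st, 2, 3, lib)
#> [1] 0.03212881

## published decoy-discrimination table: medians, best counts, Friedman
tab <- read_rank_table(system.file("extdata", "table2_itasser_ranks.tsv",
                                   package = "contactforge"))
column_median(tab, "cd")
#> [1] 79.5
best_method_counts(tab)
#>        cd any_heavy     cbeta  centroid
#>        37         4        10        10
friedman_paired(tab, "cd", "any_heavy")$p.value
#> [1] 7.895787e-10

## hybrid prediction on a synthetic alignment with planted contacts
pot <- make_random_potential(seed = 5)
sim <- make_synthetic_msa(pot, seed = 2)
raw <- hybrid_rank(sim$msa, sim$scores, NULL)   # co-evolution score alone
hyb <- hybrid_rank(sim$msa, sim$scores, pot)    # augmented by the potential
ppv_at(raw, sim$truth, N = 10)
#> [1] 0.2
ppv_at(hyb, sim$truth, N = 10)
#> [1] 0.4
```

The contact-degree value is the probability mass of mutually interfering
rotamer pairs; the rank-table statistics reproduce the published
decoy-discrimination summary (the CD-derived potential ranks the native
best in 37 of 56 cases, far ahead of the distance-based potentials); the
last two numbers show the hybrid score doubling the top-10 precision on
this alignment by promoting column pairs whose residues pair favourably
under the potential.

## Command line

```sh
contactforge cd --pdb model.pdb --rotlib rotlib.txt --cutoff 0.1
contactforge potential --pdb-list list.txt --definition cbeta --out cp.csv
contactforge hybrid --msa fam.fasta --scores di.txt --potential cp.csv
contactforge rank-stats --table ranks.tsv
contactforge simulate --what msa --seed 7 --out-dir fixtures/
```

The launcher script is installed at `exec/contactforge` inside the
package directory; every output starts with a `#` provenance header
recording the resolved definition, thresholds and seeds.

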