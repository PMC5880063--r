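---
title: "Detecting hemiclonal subgenomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hemiclonal subgenomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiclone)
```

## The biological setting

Hybridogenesis is hemiclonal reproduction: a diploid interspecific hybrid
discards one parental genome before meiosis, transmits the other genome
clonally through its gametes, and restores hybridity each generation by
mating with the sexual host species. In the water-frog system this package
models, mixed populations contain the sexual marsh frog (genotype RR, the
"R" gene pool) together with diploid hybrid males (RL) that transmit a
frozen haploid pool-frog ("L") genome and receive a fresh recombinant R
genome from sympatric RR females every generation. The mirror-image system —
sexual LL frogs with hybrids transmitting R — is supported by the same
machinery with the transmitted genome switched.

The observable consequences, and the structure the statistics exploit, are:

* every hybrid's L subgenome is (up to mutation and missing data) a copy of
  one founding haplotype — one repeated multilocus genotype;
* every hybrid's R subgenome is a fresh recombinant gamete — individually
  unique multilocus genotypes drawn from the sympatric RR gene pool;
* sexual populations are near Hardy–Weinberg equilibrium, so repeated
  multilocus genotypes are exponentially unlikely under sexuality.

## Pipeline

The analysis proceeds in the order quality → partition → clones → structure:

1. **Quality.** Per locus × population (sexual individuals only):
   a Monte-Carlo exact test of Hardy–Weinberg equilibrium and a
   maximum-likelihood null-allele frequency estimate; loci failing both
   checks can be corrected under the fitted model.
2. **Partition.** Each hybrid's diploid genotype is split into its L and R
   haploid subgenomes using registered allele species specificities;
   unclassified alleles are routed only when sympatric sexual pools decide
   the assignment unambiguously, and are otherwise surfaced as unresolved —
   never imputed.
3. **Clones.** Haploid subgenomes are self-doubled and pooled with the
   sexual residents' genotypes; exact multilocus genotypes (MLGs) are
   indexed, merged across missing data, and tested for clonality with
   P~GEN~/P~SEX~.
4. **Structure.** Nei's D~A~ distances between genome groups, UPGMA trees
   with locus bootstrap, and an allele-count PCA.

## Models

### Clonality statistics

With round-robin allele frequencies $p_a$ and per-locus inbreeding $F$, the
single-event probability of an MLG is

$$P_{GEN} = \prod_{\text{scored loci}} \begin{cases}
  p_a^2 + p_a(1-p_a)F & \text{homozygote } aa\\
  2 p_a p_b (1-F)     & \text{heterozygote } ab
\end{cases}$$

with each per-locus factor clamped to $[0,1]$ and missing loci skipped.
Round-robin frequencies at a locus are computed from one representative of
each sub-MLG defined over the remaining loci, which removes clonal
pseudo-replication from the frequency estimates; $F_{IS} = 1 -
H_{OBS}/H_{EXP}$ with $H_{EXP} = 1 - \sum_a p_a^2$ from those frequencies
(monomorphic loci take $F_{IS}=0$ by convention, estimates are clamped to
$[-1,1]$).

$P_{SEX}$ for an MLG seen $n$ times among $N$ analysed genomes is the
binomial upper tail $\sum_{i\ge n} \binom{N}{i} P_{GEN}^i (1-P_{GEN})^{N-i}$,
evaluated through the regularized incomplete beta function, which is
accurate far below $10^{-50}$. Both a per-population evaluation ($N$ =
genomes analysed from that population) and a global one ($N$ = all analysed
genomes) are reported, because the choice is a genuine analysis degree of
freedom; the verdict uses the per-population minimum. The tail may
alternatively start at $n-1$ (the probability of $n-1$ *further* sexual
draws given one observation); this convention is a switch, off by default.

A repeated MLG is called **clonal** when it has at least `min_copies = 3`
members and min-P~SEX~ ≤ `alpha = 0.05`; **putative** when it is repeated
but only one of the two conditions holds; otherwise **sexual**. Three copies
is the classical field threshold for declaring clonal inheritance of a
multilocus genotype; two identical genotypes can plausibly arise sexually
when alleles are common.

**Self-doubling identity.** Haploid subgenomes are re-coded as homozygous
diploids before the clonality statistics. At $F=1$ the homozygote factor
reduces to $p_a$, so $P_{GEN}$ of a doubled haploid is exactly the haploid
product of its allele frequencies — doubling introduces no distortion, it
only lets haploid and diploid records share one machinery. The test suite
asserts this identity analytically.

**Pooling.** Clonal repetition is judged *relative to the allele frequencies
of the analysed record set*. A pure clone set analysed alone is degenerate
(its alleles have frequency 1 and $P_{GEN}=1$), so `detect_clones()` is
documented to take the genomes under test pooled with the sexual reference
individuals — matching how clonality programs are run in practice.

### MLG merging across missing data

Exact MLG equality treats a missing slot as a state, so clone copies with
sporadic dropout fragment into several exact MLGs. Merging uses a
compatibility graph: two MLGs are compatible when the scored part of each
cell is nested in the other's at every co-scored locus and they share at
least `min_shared_loci = 5` co-scored loci (preventing vacuous merges of
mostly-missing records). A connected component is merged only when it is a
clique, in which case the per-locus most-complete cells form a unique,
conflict-free consensus. Non-clique components (e.g. a chain A–B–C where A
and C conflict) are *split into maximal cliques* — transitive merging is
deliberately rejected, because one intermediate, mostly-missing record must
not chain two genuinely different genotypes into one clone. Cliques are
chosen greedily, largest membership first, ties by lexicographically
smallest consensus key; every split is logged in the result object.

### Hardy–Weinberg screening

The exact test conditions on the observed allele counts: the p-value is the
probability, under the multinomial genotype model, of a genotype
configuration at most as probable as the observed one. The null distribution
is sampled by permuting the $2n$ allele copies among individuals
(`n_reps = 10000` by default, seeded), with
$p = (1 + \#\{\text{permuted} \le \text{observed}\})/(n_{reps}+1)$.
Monomorphic loci return $p = 1$ by convention. The test suite checks the
Monte-Carlo p against full enumeration of all pairings at small $n$ and
checks approximate uniformity of p under simulated equilibrium data.

### Null alleles

The estimator fits the HWE-with-null three-class model — visible
heterozygote $2p_ip_j$, visible homozygote $p_i^2 + 2p_i r$, blank $r^2$,
with $\sum_i p_i = 1-r$ — by EM, treating the null as an extra allele and
blank (nonamplified) cells as data, namely null homozygotes. Half-scored
cells are excluded. Numerical details: EM tolerance $10^{-8}$ on $r$; a
boundary polish compares the fitted likelihood against the $r=0$ model and
returns 0 when the boundary explains the data equally well (EM converges
only geometrically near that boundary); when no cell is visible the estimate
is the boundary value $r = 1$; with a single visible allele the ML estimate
coincides with the moment estimator $\sqrt{\text{blank fraction}}$, which
the tests assert.

A locus is *flagged* when $\hat r \ge 0.05$ **and** the HWE p-value is
below 0.05 with a heterozygote deficit — a conjunction, because a
heterozygote deficit alone can reflect substructure and blanks alone can
reflect handling. The **correction** recodes blanks as homozygotes for a
reserved null state and, additionally, reassigns each apparent homozygote
$aa$ to $(a,\text{null})$ with the fitted posterior probability
$2r/(p_a+2r)$ (seeded). The second step is this package's formalization of
the usual "adjust for nulls" procedure: without it the corrected data still
fail any exact HWE test (the visible-homozygote class stays inflated and the
null-heterozygote class stays empty), whereas the model-based reassignment
makes corrected data re-screen clean, which the acceptance tests verify by a
Kolmogorov–Smirnov check of p-value uniformity over 200 simulations. The
correction is idempotent: corrected (locus, population) pairs are recorded
and skipped on re-application.

### Taxon assignment and hybrid index

Taxon calls use only species-classified alleles: each informative locus is
classified LL/RR/RL by its allele composition, the call is the majority
class, and calls with support below `min_support = 0.75` are reported
ambiguous rather than guessed. Discordant loci (e.g. an R-specific allele in
an otherwise pure LL genotype) are listed, never reinterpreted — whether
such alleles are introgression or ancestral polymorphism is not decidable
from marker data alone.

The hybrid index replaces Bayesian admixture clustering with a supervised
two-source likelihood, which is the appropriate tool when parental reference
panels are available: $\hat q$ maximizes $\sum_a \log(q f_R(a) + (1-q)
f_L(a))$ over the individual's scored allele copies, with parental
frequencies pseudo-counted at $\varepsilon = 0.5/(2N)$ per registered allele
so the likelihood stays finite. The likelihood is concave; it is maximized
by 1-D optimization to $10^{-6}$ with explicit boundary comparison, and a
flat likelihood (all $f_R = f_L$) is flagged instead of silently returning
an arbitrary interior point. This reproduces the qualitative trichotomy of
$q$ values (parental ≈ 0/1, hybrids intermediate), not any particular MCMC
implementation's numbers.

### Subgenome partitioning

Routing at each locus: alleles classified to different genomes go to their
genomes; an unclassified (shared/nonspecific) allele is routed to the
remaining genome only if it occurs in the sympatric sexual pool of that
genome's species (resolution `pool-resolved`); otherwise the locus is left
`unresolved` and surfaced. Two alleles classified to the same genome are a
logged conflict. Loci amplifying in a single genome contribute one allele to
that genome and a missing slot to the other. The sympatric pool is
per-population by default (alleles observed in sexual individuals of the
same population), widenable to the system-wide pool; the pool-membership
rule is this package's quantitative formalization of the visual
plausibility check used in field studies ("the sexually inherited allele
must occur in the sympatric sexual gene pool"), and alleles violating it are
flagged per individual. Partitioning is deterministic and
order-independent; with disjoint allele bands and no mutation it recovers
the simulated truth at every locus, which the tests assert.

### Distances, trees, ordination

Nei's $D_A$ between genome groups is $1 - \frac{1}{L}\sum_{loci}\sum_a
\sqrt{x_a y_a}$ on sample allele frequencies; loci unscored in any group are
dropped and logged, and cross-genome comparisons should exclude loci that
amplify in a single parental genome (the pipeline does). UPGMA is the
classic size-weighted average-linkage agglomeration, implemented directly so
the tie-break is part of the contract (smallest label pair
lexicographically, labels being each cluster's smallest member); tie-free
results are verified against average-linkage `hclust` on a thousand random
matrices. Branch support resamples loci with replacement (default 7000
replicates, seeded, bit-reproducible), recomputes $D_A$ + UPGMA, and scores
each original clade by the fraction of replicates containing the same leaf
set; trees are `ape` `phylo` objects and export to Newick with support as
node labels.

The PCA codes records as entity × allele-count columns (diploid 0/1/2;
haploid and half-scored cells coded 0/2 to match the self-doubling
convention), imputes missing cells with the column mean, centres and
standardizes columns (zero-variance columns dropped), and reports axes
strictly by eigenvalue rank with their explained-variance percentages.
Display conventions of legacy spreadsheet tools that number axes differently
are not followed, so axis percentages are comparable only by rank.

## The synthetic-data generator

`sim_config()` defaults define the emulated study conditions:

* **Populations**: five mixed populations holding sexual RR frogs of both
  sexes (17/1/8/6/9) and all-male hybrids (12/2/4/4/5) — the composition of
  a small river-valley survey of an all-male hybrid system. The mirror L–E
  system (LL residents, hybrids of both sexes transmitting R) is generated
  by the same engine with the transmitted genome switched.
* **Loci**: 17 microsatellite-style loci, 3 amplifying only in the L genome
  and 3 only in R, the rest in both, with disjoint per-species allele-size
  bands (motif step 2) and 6–17 founder alleles per locus per species,
  frequencies drawn Dirichlet(1).
* **Inheritance**: each hybrid carries one founding clonal haplotype
  (`n_clones = 1`), optionally mutated along `generations` clonal
  transmissions under a stepwise model (±1 motif step, equal probability,
  rate per gamete per locus, default 0), plus a recombinant gamete drawn
  from the sexual pool's frequencies. Sexual genotypes are drawn with
  inbreeding coefficient `fis_sexual` (default 0):
  $P(aa) = p_a^2 + F p_a(1-p_a)$, $P(ab) = 2p_ap_b(1-F)$.
* **Artifacts**: whole-cell missingness at `missing_rate = 0.02`; null
  alleles per locus with probability `null_allele_rate` (default 0) at
  frequency `null_freq = 0.2`, applied per allele copy so null homozygotes
  blank the cell and null heterozygotes masquerade as visible homozygotes —
  exactly the observable classes the estimator fits.

One root seed drives everything; per-population substreams are derived
deterministically, and the truth log records founding haplotypes, clone
membership, mutation events and injected artifacts, so any dataset is
replayable bit-identically.

What the generator does **not** emulate: allele-size homoplasy across
species (bands are disjoint, so species specificity is perfect —
partitioning on real data with shared alleles leans on the pool rule far
more than simulated data do); linkage and null-allele correlation across
loci; genotyping error other than dropout; population structure within a
species (one species-wide frequency pool); ecological dynamics, mate choice
and triploids. Passing tests therefore demonstrate correctness of the
inference machinery under the stated statistical structure, not robustness
to every artifact of real capillary data.

## Numerical and design choices

* P~SEX~ through `pbinom(..., lower.tail = FALSE)` (incomplete beta), not a
  naive sum; verified against log-sum-exp and enumeration oracles.
* EM boundary polish (above); homozygote-vs-half-call ambiguity is never
  auto-resolved — a single-allele cell is stored as (allele, missing) and
  doubling is an explicit, named operation with two documented modes.
* Merge tie-break and UPGMA tie-break are deterministic and documented;
  merged output order is by consensus key, so runs are reproducible
  independent of input order.
* Degenerate inputs: monomorphic loci ($p=1$, $F_{IS}=0$), empty registries,
  all-missing records, all-blank loci ($\hat r = 1$), and identical-record
  PCA (all eigenvalues 0) all have defined behaviour under test.
* Default thresholds: `alpha = 0.05`, `min_copies = 3`,
  `min_shared_loci = 5`, null flag at $\hat r \ge 0.05$ plus HWE rejection,
  bootstrap 7000.

## Problem sizes used by the test suite

The suite exercises the statistics at sizes chosen to make sampling error
negligible relative to the asserted tolerances while keeping the default run
fast: end-to-end recovery over 100 simulated systems of 60 individuals × 10
loci; null-allele recovery over 200 replicates at $n = 500$; HWE uniformity
over 200 simulations with 499 permutations each; UPGMA oracle equivalence
over 1000 random 4-leaf matrices; P~SEX~ enumeration for all $N \le 10$. The
acceptance script repeats these from a command-line seed and additionally
runs the full pipeline at the default study-scale composition with the full
7000-replicate bootstrap.

## Known limitations

* No somatic-genotyping-error tolerance in MLG matching (no "maximum number
  of differing loci" slider): compatibility is exact-or-missing. A clone
  with a scoring error at a co-scored locus will appear as a second clone.
* The null-allele correction imputes under the fitted model; downstream
  statistics on corrected loci inherit that model assumption.
* P~SEX~ assumes the analysed genomes are exchangeable draws from one gene
  pool; strong substructure inflates significance.
* The supervised hybrid index requires parental reference panels; it does
  not discover unknown source populations.
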