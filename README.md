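# hemiclone

Detection of clonally transmitted (hemiclonal) subgenomes in diploid hybrid
populations from co-dominant marker genotypes.

## The problem

Hybridogenetic hybrids are "sexual parasites": a diploid hybrid excludes one
parental genome from its germline, transmits the other as a frozen haploid
clone, and regains hybridity every generation by mating with the sexual host
species. In European water frogs (*Pelophylax*), mixed populations can consist
of a sexual species plus hybrids whose clonally transmitted half is invisible
to ordinary population-genetic tools: each hybrid is heterozygous, half its
genome recombines every generation, and the other half is copied.

Given microsatellite-style genotype tables (individual × locus, one or two
integer alleles per cell, missing allowed), a registry of species-specific
alleles, and population metadata, this package answers, with tested and
reproducible code:

* which individuals are parental (LL / RR) and which are hybrids (RL), and
  how admixed each genome looks (a supervised hybrid index);
* how each hybrid's diploid genotype splits into its two parental haploid
  subgenomes, using allele species specificity and sympatric sexual pools;
* whether any subgenome is repeated beyond sexual expectation — the core
  clonality inference; and
* how the clonal genomes relate to the sympatric sexual gene pools
  (Nei *D<sub>A</sub>* distances, UPGMA trees with locus bootstrap, PCA).

A first-class synthetic-data generator simulates whole hybridogenetic
population systems with known ground truth, so every stage of the pipeline is
verifiable without field samples.

## The core statistics

A **multilocus genotype (MLG)** is the exact combination of alleles across
loci. Exact MLGs that differ only through missing data are merged under a
conservative clique rule (no conflict at any co-scored locus, a minimum
number of co-scored loci, no transitive merging).

Allele frequencies are estimated by the **round-robin** method: at each locus,
sub-MLGs are formed over all *other* loci and one representative per sub-MLG
contributes copies, removing clonal pseudo-replication. From these
frequencies, per-locus inbreeding is *F*<sub>IS</sub> = 1 −
*H*<sub>OBS</sub>/*H*<sub>EXP</sub>.

**P<sub>GEN</sub>**, the probability that a given MLG arises in a single
sexual reproductive event, is the product over scored loci of the
*F*-corrected genotype probability:

* homozygote *a*: *p<sub>a</sub>*² + *p<sub>a</sub>*(1 − *p<sub>a</sub>*)*F*
* heterozygote *ab*: 2 *p<sub>a</sub> p<sub>b</sub>* (1 − *F*)

For a self-doubled haploid subgenome (*F* = 1) this reduces to the haploid
product of allele frequencies — the identity that justifies analysing haploid
subgenomes with diploid machinery.

**P<sub>SEX</sub>**, the probability that an MLG observed *n* times among *N*
analysed genomes derives from *n* independent sexual events, is the binomial
upper tail at *P*<sub>GEN</sub>, computed both per population and globally.
A repeated MLG is called **clonal** when it has at least 3 copies and its
smallest per-population *P*<sub>SEX</sub> is below α = 0.05.

Upstream of this, each locus × population cell is screened for
Hardy–Weinberg departure (seeded Monte-Carlo exact test) and null alleles
(maximum-likelihood fit of the HWE-with-null three-class model, blanks
treated as data, i.e. as null homozygotes), with an optional model-based
correction.

## Worked example

Simulate an all-male hybrid system (five mixed populations, 41 sexual RR
frogs and 27 hybrid males carrying one clonal L haplotype, 17 loci of which
three amplify only in each single parental genome), partition the hybrids,
and run the clone detection on the pooled record set:

```r
library(hemiclone)

cfg  <- sim_config(seed = 7)
sim  <- inject_artifacts(simulate_re_system(cfg), cfg)
ds   <- sim$dataset
part <- partition_hybrids(ds)            # split RL genotypes into L | R haploids
pooled <- bind_datasets(
  subset_dataset(ds, which(ds$ind$taxon == "RR")),
  double_haploid(part$L, "self-double"),
  double_haploid(part$R, "self-double"))
fit <- detect_clones(pooled)
print(fit)
```

```
Clone analysis: 74 exact MLGs -> 69 merged MLGs
  verdicts: clonal 1  putative 0  sexual 68
  MLG069: 27 copies, P_GEN = 1.13e-15, P_SEX = 3.42e-170 (min) / 0 (global)
```

Reading the output: among 95 pooled records (41 RR genotypes + 27 doubled L
subgenomes + 27 doubled R subgenomes) the analysis finds one MLG repeated 27
times — every hybrid's L subgenome — whose probability of arising 27 times
from independent sexual events is astronomically small (the global value
underflows double precision), while all 27 R subgenomes and all RR genotypes
are unique, i.e. sexual. That is the hemiclonal signature: a Mendelian R
genome riding on a frozen clonal L genome.

`run_pipeline(pipeline_config(seed = 7))` runs the same analysis plus HWE /
null-allele screening, the DA/UPGMA bootstrap tree and the PCA, and writes
TSV/Newick/JSON artifacts with a machine-readable manifest.

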