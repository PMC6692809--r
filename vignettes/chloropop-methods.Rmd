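---
title: "Methods: haploid chloroplast population genomics with chloropop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haploid chloroplast population genomics with chloropop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloropop)
```

`chloropop` analyses variation on the rice chloroplast genome — a maternally
inherited, effectively haploid, non-recombining ~134.5-kb circle — across
hundreds of accessions spanning cultivated subgroups (*indica*, temperate and
tropical *japonica*, *aus*, aromatic, admixed) and wild relatives. This
vignette documents the statistical machinery, the choices behind it, and what
the synthetic-data generators do and do not emulate.

## The genotype container and filtering

All statistics operate on a `chloro_geno`: a site table (position, REF/ALT
alleles, SNP/InDel class, transition/transversion type) plus an integer
matrix of haploid allele calls with `NA` for missing. Organelle variant
callers often emit diploid-coded genotypes; homozygous calls collapse to one
allele and heterozygous calls — biologically implausible on a haploid
plastome and usually mapping artifacts — become missing by default
(`het = "major"` keeps the first allele instead).

The high-quality filter removes sites with more than 20% missing calls or a
minor allele frequency below 0.01. Both comparisons are strict (`>` and `<`),
so sites exactly at either boundary are retained; MAF is computed among
non-missing calls, and for multiallelic sites it is the frequency of the
second-most-common allele. The filter is idempotent and order-preserving.

## Diversity, FST, Tajima's D

**Nucleotide diversity.** Windowed pi sums the unbiased per-site
heterozygosity $\frac{n_i}{n_i-1}\left(1-\sum_a p_a^2\right)$ over the
variant sites of a window and divides by the window length (invariant
positions count in the denominator), giving diversity per bp on the
$10^{-8}$–$10^{-3}$ scale typical of plastomes. Windows are anchored at
position 1; the defaults (1000-bp windows, 500-bp steps) match common
VCF-tool practice, and a 500/500 grid is available where a finer picture is
wanted. Per-site sample sizes $n_i$ use non-missing calls only; a window
whose every site lacks two callable alleles reports `NA`, and a window with
no variant sites reports 0. This quantity equals the mean pairwise
difference per site — the test suite checks that equivalence against a
brute-force pair enumeration at $10^{-12}$ tolerance.

**FST.** `weir_cockerham_fst()` is the Weir–Cockerham (1984) ANOVA
estimator specialised to haploid data, where each sequence contributes a
single allele and only two variance components survive: among groups ($a$)
and within groups ($b$). Per site and allele,
$MSP = \sum_i n_i(p_i-\bar p)^2/(r-1)$,
$MSG = \sum_i n_i p_i(1-p_i)/\sum_i(n_i-1)$,
$n_c = (N-\sum n_i^2/N)/(r-1)$, $a=(MSP-MSG)/n_c$, $b=MSG$; components sum
over alleles, sites monomorphic across the pooled pair are skipped, and the
genome-wide "weighted" estimate is $\sum a / \sum(a+b)$. Planted fixed
differences give exactly 1; identical allele frequencies give small negative
values — the estimator's well-known finite-sample behaviour (comparing a
group against itself yields exactly $-1/(n_c-1)$, not 0).

**Tajima's D** uses the 1989 constants computed from the subset sample
size, with $\hat\pi$ as the mean pairwise difference count (per-site
non-missing denominators) and $S$ the segregating-site count. $D$ is
undefined at $S=0$. The whole-genome value per group is the default — the
chloroplast is one linkage block, so windowed D values are strongly
correlated; a windowed mode on the same 1000/500 grid is provided for
comparability with windowed diversity.

**Ordinations.** PCA is an eigen-decomposition of the covariance of the
mean-centred allele-count matrix, missing calls imputed to site means; MDS is
classical metric scaling of normalised pairwise mismatch (Hamming) distances
with missing pairs excluded per comparison. Both are deliberately plain
re-implementations of what genotype-matrix tools do, so group separation is
attributable to the data rather than to preprocessing.

## Selection scan

The diversity-reduction scan forms per-window ratios $\pi_w/\pi_c$ between a
reference group (wild rice by default) and a focal cultivated group. The
source text is ambiguous about whether the ratio contrasts wild/cultivated
or *indica*/*japonica*; both pairings are runnable because the groups are
arguments, and nothing is hard-coded. Windows where the denominator falls
below a floor (`1e-9`) are excluded from ranking rather than mapped to
infinity, so monomorphic windows cannot dominate. The candidate cutoff is
the top 2.5th percentile of defined ratios (linear interpolation, type-7
quantile); ties at the cutoff are all selected (conservative), and adjacent
or overlapping selected windows merge into regions. Without ties the
selected-window count is exactly `ceiling(n * 0.025)`.

## Haplotypes and the statistical-parsimony network

Samples with identical allele vectors over the retained sites form a
haplotype; InDels count as ordinary multi-state sites by default (switchable
to SNP-only), since the chloroplast's variant set travels as one
non-recombining unit. Samples with any missing call are excluded from
collapsing by default: missing-tolerant matching can declare A = B and B = C
while A differs from C, and a non-transitive "identity" makes haplotype
counts ill-defined.

The network follows the TCS statistical-parsimony recipe: candidate pairs
are joined in increasing Hamming distance (ties prefer higher-frequency
haplotypes, then lower index — output is deterministic), a `d`-step
connection inserts `d − 1` inferred intermediate nodes so each edge is one
mutational step, and pairs beyond the parsimony limit stay in separate
components.

The parsimony limit itself comes from a probability model derived here from
first principles: mutations hit each site as an independent Poisson process;
for a pair differing at $j$ of $L$ sites the per-site rate is estimated
Jukes–Cantor-style as $\lambda=-\log(1-j/L)$; conditional on a site showing
a difference, the chance it was hit exactly once is
$r=\lambda(1-j/L)/(j/L)$, and the connection is parsimonious with
probability $r^j$. The limit is the largest $j$ keeping $r^j$ above the
confidence level (0.95 by default); it grows like $\sqrt{L}$ and evaluates
to 117 steps for the 134,525-bp chloroplast. A Monte-Carlo evaluation of the
same model serves as the independent oracle in the tests.

## Introgression scan

Derived (non-reference — no outgroup polarisation is attempted) allele
frequencies are computed per group; a site is *japonica*-specific when its
frequency is strictly above 0.95 in *japonica* and strictly below 0.05 in
*indica*, and vice versa. Presence of the derived allele in wild rice is
recorded as a flag by default and only removes sites under
`exclude_wild = TRUE`, because the "undetected in wild rice" condition is a
description rather than a formal rule in the source analysis. Per-accession
profiles count carried opposite-type alleles; the candidate-introgressant
verdict uses a declared 0.10 opposite-fraction threshold — no published
value exists, so the threshold is a configurable default, not a claim.

## Heterozygosity-excess bottleneck test

After a recent contraction a population loses allele count faster than gene
diversity, so observed heterozygosity exceeds the equilibrium expectation
*given the number of alleles still present*. For each locus with $k \ge 2$
alleles among $n$ calls, `simulate_heq()` draws coalescent samples under a
mutation model, keeps replicates with exactly $k$ alleles, and summarises
their unbiased heterozygosity; `het_excess_test()` standardises the observed
value against that distribution (DH) and combines loci with a sign test
(reference proportion estimated from the same simulations) and a one-tailed
Wilcoxon signed-rank test for excess.

Model specifics: IAM replicates are drawn exactly by the Ewens/Hoppe urn
with theta solved from the Ewens expected allele count — equivalent to
simulating the genealogy and placing infinitely-many-alleles mutations, and
much faster. SMM and TPM simulate the Kingman genealogy explicitly and walk
an integer allele ladder; TPM mixes single steps (probability 0.70) with
geometric multi-steps (variance 30), both exposed as arguments. These two
models exist for microsatellite-style loci; chloroplast SNPs are not
microsatellites, and the models are provided to mirror the three-model
design of the classic program, caveat documented here. Theta for SMM/TPM is
calibrated by stochastic bisection on the simulated mean allele count, then
rejection sampling conditions exactly on $k$; loci sharing a $(k, n)$ class
reuse one simulation. Seeds are explicit arguments throughout.

Two honest caveats. First, the MAF ≥ 0.05 pre-filter of the original
pipeline truncates low-heterozygosity loci and biases the null towards
excess; calibration experiments in this package therefore run without it,
while `prefilter_loci()` remains available to mirror the published
workflow on real data. Second, DH under the null is skewed (especially at
$k=2$, where the conditional heterozygosity distribution is strongly
asymmetric), so the one-tailed Wilcoxon signed-rank — which assumes a
symmetric null — runs slightly hot: measured over 200 constant-size
datasets, 8.5% of nulls reject at nominal 5% (95% CI 5–13%). This is a
property of the method's construction, not of this implementation, and is
left as is.

## Ka/Ks

`pairwise_kaks()` implements Nei–Gojobori (1986) counting with the standard
genetic code (which chloroplast protein genes use): per-codon synonymous
site fractions (changes to stops count as nonsynonymous, so $n+s=3$ per
sense codon), differences averaged over all orderings of single steps for
multi-hit codons with pathways through stop codons excluded, and the
Jukes–Cantor correction $K=-\tfrac34\log(1-\tfrac43 p)$. $\omega = K_a/K_s$
is undefined at $K_s=0$; classifications follow the study's thresholds
($\omega>1$ accelerated, $\omega<1$ purifying, $\omega>5$ outlier). This
counting method deliberately replaces the likelihood branch-model machinery
of the original analysis (which needs a species tree and foreground/
background branch assignments); counts of accelerated/purifying genes from
the two approaches need not coincide.

## Synthetic data: what it emulates, and what it does not

`simulate_coalescent()` is a neutral infinite-sites Kingman coalescent
(exponential coalescence at rate $j(j-1)/2$, Poisson mutations at
$\theta/2$ per branch-length unit), with sites mapped to unique uniform
positions so windowed statistics see realistic coordinates. Its calibration
is a joint check of simulator and statistics: at $n=10$, $\theta=5$, 500
replicates, mean $S$ matches $\theta a_1$ and mean $\hat\pi$ matches
$\theta$ within 5%, and mean Tajima's D sits within 0.15 of zero.

`simulate_structured()` builds the study-shaped dataset: seven subgroups at
the published sample sizes (66 *indica*, 253 temperate and 25 tropical
*japonica*, 9 *aus*, 2 aromatic, 3 admixed, 54 wild), per-group theta chosen
once to reproduce the qualitative diversity ordering (wild ≫ *indica* >
*japonica*, with *indica* roughly twice *japonica*: 30, 4, 1.5/1.5, 5, 0.5,
0.5, 30 for wild), ten planted fixed differences between *indica* and the
*japonica* pair standing in for the deep cytoplasm divergence, 2% missing
calls, a 12.2% InDel share and a 63.7% transition bias among SNPs — the
latter three taken from the published variant summaries. Group
polymorphism is private by construction (each group draws its own
genealogy); there is no shared ancestral polymorphism, no gene flow, and no
recombination (the chloroplast has none to emulate, but the absence of
shared variation means FST values on synthetic data run higher than real
inter-subgroup values at the same theta).

`simulate_bottleneck_dataset()` generates *unlinked* neutral sites — each
site its own genealogy, $S\sim\mathrm{Poisson}(\theta a_1)$, derived counts
on the $1/i$ spectrum — then prunes each site with probability
$\mathrm{severity}\times(1-2\,\mathrm{maf})$. Pruning rare variants faster
than common ones is precisely the allele-count-versus-diversity distortion
the bottleneck test detects; severity 0 is exactly neutral. Unlinked sites
are used deliberately: the test combines loci as independent, and a single
shared chloroplast genealogy would violate that assumption by construction,
so these datasets emulate the test's own sampling model rather than one
physical plastome. Power-study conditions (20 datasets, $n=30$,
$\theta=20$, severity 0.8, 300 accepted replicates per locus class) were
fixed from a design pilot: type-I retention 20/20 and power 19/20 there.

Passing tests on these generators demonstrate correctness of the machinery
and recoverability of planted signals; they do not demonstrate that real
rice data satisfy the generators' assumptions (no gene flow, no shared
ancestral variation, unlinked bottleneck loci, uniform missingness).

## Numerical details and degenerate inputs

Quantiles use R's type-7 interpolation. Percent thresholds in the
introgression scan are strict inequalities, as are both filter boundaries.
Hamming distances exclude missing pairs and normalise by compared sites;
all-zero distance matrices produce a single-point MDS with a warning. The
`tstv_ratio()` of a transversion-free matrix is `Inf` rather than an error.
`simulate_heq()` aborts when rejection acceptance falls below 1% of the
attempt budget rather than silently returning a thin sample. Network
construction is deterministic: pair order is (distance, larger size,
smaller size, index).

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
the 412-accession study-shaped simulation, 500-replicate coalescent
calibrations, 20-dataset bottleneck operating-characteristic studies, and
toy matrices up to 12 samples x 50 sites for exact-oracle comparisons.
These sizes give stable Monte-Carlo estimates while keeping a full run in
the order of a minute on one CPU.
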