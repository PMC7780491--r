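---
title: "Co-expression modules and rare-variant burden: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression modules and rare-variant burden: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`migmod` implements an integrated systems-genetics analysis: gene
co-expression modules are discovered from expression data, rare functional
variants segregating with disease are called in multi-generation pedigrees,
each module is tested for an excess of mutated genes, candidate modules are
replicated in independent case and control cohorts, and surviving modules
are annotated by cell-type and pathway enrichment. This vignette describes
the statistical machinery, the parameters that matter, and the design
choices made where the methodology left genuine freedom.

## Network construction

### Gene selection and soft thresholding

Genes enter the network by *connectivity*: for gene $i$,
$k_i = \sum_{j \ne i} |\mathrm{cor}(x_i, x_j)|$ under Pearson correlation,
and the top $k$ genes (default 5000) are retained. The weighted network is
unsigned: the adjacency is $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with a
unit diagonal. Pearson correlation and the unsigned transform are the
conventional defaults for this class of analysis; signed and
biweight-midcorrelation variants are deliberately out of scope.

The power $\beta$ is chosen against the scale-free topology criterion.
Connectivities at each candidate power are binned into 10 equal-width bins;
the signed fit statistic is the $R^2$ of $\log_{10} p(k)$ on
$\log_{10} \bar k$ across occupied bins, with the sign of the slope flipped
so a decreasing, power-law-like relationship scores positive. The chosen
power is the smallest candidate whose signed $R^2$ reaches the target
(default 0.8); if none qualifies the best-fitting power is used with a
warning. Equal-width binning is essential: with equal-count bins the
regression response is constant by construction and the statistic is
meaningless.

Two practical notes. First, the default candidate grid is 1–20, but small
networks (a few hundred genes) often need higher powers before the
criterion is met — the recovery experiments in the test suite scan 1–30 and
typically settle near $\beta \approx 20{-}25$ on the 450-gene synthetic
fixture, whereas multi-thousand-gene networks usually satisfy the criterion
in the standard range. Second, $\beta$ is fitted **once on all samples and
then frozen**: refitting inside the resampling loop described next would
make the resampled networks non-comparable.

### Consensus topological overlap

The clustering dissimilarity is one minus the topological overlap
$$
  w_{ij} \;=\; \frac{\ell_{ij} + a_{ij}}
                    {\min(k_i, k_j) + 1 - a_{ij}},
  \qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},
$$
which rewards shared network neighborhoods rather than raw pairwise
correlation. To stabilize the network against individual samples, the TOM
dissimilarity is recomputed on `n_resamples` (default 100) random subsets
of the samples, each leaving out a fixed fraction (default 10%, drawn
without replacement — a true leave-out, not a bootstrap), and averaged
element-wise. With a leave-out fraction of zero the consensus equals the
full-data TOM exactly, which the tests use as an anchor. Fully disconnected
pairs (non-positive denominator) get dissimilarity 1 by convention.

### Module detection

Genes are clustered by average-linkage hierarchical clustering of the
consensus dissimilarity, and modules are pruned from the dendrogram
adaptively. A fixed cut height does not transfer across powers: unrelated
gene pairs concentrate in a narrow high-dissimilarity band whose location
(and width) depends strongly on $\beta$ — near 0.99 at $\beta = 6$ but
within $10^{-6}$ of 1 at $\beta = 23$ on the same data. Detection therefore
works in three scale-free steps:

1. **Branch scan.** Every cut height of the dendrogram (equivalently, every
   prefix of the merge sequence) is scored by the number of branches with
   at least `min_module_size` genes (default 30), and the lowest height
   attaining the maximum is chosen. This finds the tight branch cores
   wherever they sit on the height axis.
2. **Pruning.** Within each core, a member whose mean dissimilarity to the
   rest of the core sits at the background level (the median off-diagonal
   dissimilarity) is dropped: such genes are late-joining hitchhikers on an
   otherwise tight branch. The retention rule is relative — a member must
   close at least $\theta = 0.25$ of the gap between the background level
   and the core's mean internal dissimilarity. Cores falling below the
   minimum size are dismissed entirely, which is what keeps a planted
   29-gene cluster grey at a 30-gene minimum even when a stray background
   gene attaches to its branch.
3. **Completion.** Unassigned genes are attached to the nearest core under
   the same relative-margin rule, recovering branch periphery without
   absorbing background genes.

Genes in no surviving branch take the reserved "grey" label. Modules are
named by the conventional color sequence in decreasing size order, so
"turquoise" is always the largest. No eigengene-based module merging is
performed. The procedure is deterministic and invariant to gene input
order up to label permutation.

### Permutation validation

Each module's mean pairwise topological overlap is compared with the same
statistic for random gene sets of identical size drawn from the network
(default 1000 permutations). The empirical one-sided p-value uses add-one
smoothing, $p = (1 + \#\{\text{perm} \ge \text{obs}\}) / (1 + B)$, so it is
never exactly zero; the grey set is tested like any module. The permutation
count is a package default — the underlying methodology does not fix one.

A caution on very high powers: overlap magnitudes scale like
$|\mathrm{cor}|^{2\beta}$, so at $\beta$ above ~20 a module whose realized
mean correlation is slightly below its neighbors' can have absolute overlap
at the background level even though the *relative* structure still supports
its detection. The calibration experiments in the test suite therefore
validate at a moderate fixed power (6); on real multi-thousand-gene
networks, where chosen powers are far lower, the distinction rarely
matters.

## Rare-variant segregation

Variants are consumed from VCF with per-gene consequence and population
allele-frequency annotations (multi-allelic sites split, per-allele INFO
respected, phased and unphased genotypes read identically as dosage,
half-missing calls treated as missing). A variant *qualifies* when

- its consequence is one of the eight functional classes (frameshift and
  non-frameshift indels, non-synonymous SNVs, splice-site, stop-gain,
  stop-loss), and
- its population MAF is strictly below the threshold (default 5%), with a
  missing frequency counting as rare — absence from a large reference
  database is itself evidence of rarity. The companion
  `max_credible_af()` calculator reproduces the standard maximum-credible
  allele-frequency formulas for monoallelic and biallelic architectures,
  from which a cut-off of this magnitude follows for a common disease with
  modest allelic heterogeneity.

Segregation in a family follows an explicit dominant rule with a penetrance
bound: the variant segregates iff (a) every affected member with a
non-missing genotype carries at least one alternate allele, and (b) among
genotyped members of known phenotype, the fraction of carriers that are
affected is at least `penetrance_min` (default 0.9). Members of unknown
phenotype are excluded from both counts. This is a transparent surrogate
for composite-likelihood pedigree tests whose internals are not part of
this package's scope; only the lower penetrance bound of the published
0.9–1 range enters the rule, since the upper bound does not constrain a
carrier-fraction criterion.

Per gene, the familial caller reports `mutated` (some qualifying variant
segregates in at least one family), `non_mutated` (variants observed, none
qualifying), or `undetected` (no variants at all — such genes are excluded
from burden testing because nothing could have been observed for them).
The per-gene family count counts *families*, not variants. The cohort
caller used for replication drops the segregation requirement: one carrier
of a qualifying variant suffices.

## Burden testing, intolerance filter, and replication

Modules whose mutated genes are unusually *tolerant* of functional
variation are excluded before burden testing: a one-sided Welch t-test per
module of mean intolerance score (e.g. RVIS; higher = more tolerant) in
mutated vs non-mutated genes, excluding at p < 0.05. Welch rather than
pooled-variance is used because group sizes and variances differ widely; if
both groups are constant the t-statistic is undefined and a direct mean
comparison decides.

Each retained module is tested with a one-tailed Fisher exact test on the
2×2 table of mutated/non-mutated genes inside vs outside the module, over
all network genes with detectable variation (grey genes stay in the
background: detectability, not module membership, is the only restriction).
The p-value is the exact upper hypergeometric tail $P(X \ge a)$ — computed
from binomial-coefficient products when they fit in double precision, which
keeps small tables exact to the last bit, with a log-space fallback for
large ones. The odds ratio is the plain cross-product, with the
Haldane–Anscombe +0.5 correction applied to all cells only when a zero cell
occurs, and only for the odds ratio and its log-normal 95% CI — never for
the exact p-value, which needs no correction. P-values are Bonferroni
multiplied by the number of tested modules and capped at 1; a module is
significant at adjusted p < 0.05.

Replication runs the cohort caller and the same burden test separately in
an independent case cohort and a population control cohort — never pooled,
to avoid batch and processing artifacts — with Bonferroni over the same
candidate set in each arm. A module *replicates* iff it is significant in
cases and not in controls.

## Functional annotation

**Cell-type enrichment.** From a cell-type mean-expression matrix, the
specificity of gene $g$ for type $c$ is its mean expression in $c$ divided
by its summed mean expression over all types (rows sum to 1; all-zero genes
are dropped). The statistic for a gene set is its summed specificity per
type, compared against `n_bootstrap` (default 10 000) equally sized random
gene sets with add-one-smoothed empirical p-values. Bootstrap sets are
drawn uniformly, without expression-level matching; matching is an
extension point, and the uniform null is the appropriate reference for the
synthetic fixtures used here.

**Pathway over-representation.** For a pathway with $K$ genes in a
reference universe of $N$ (the network gene list), a query of $n$ genes
overlapping in $k$ scores $p = P(X \ge k)$, $X \sim
\mathrm{Binomial}(n, K/N)$; an empty overlap gives $p = 1$ exactly.
Benjamini–Hochberg FDR is applied across pathways, and for consistency
across cell types as well; significance is adjusted p < 0.05.

## Synthetic data and what passing tests mean

The generators provide every input with known ground truth:

- **Expression.** Each planted module is driven by one latent
  standard-normal sample vector; member genes are
  $\sqrt{r}\,e_m + \sqrt{1-r}\,\varepsilon$, so the expected within-module
  correlation is exactly $r$ (default study condition $r = 0.7$, five
  modules of 50 genes, 200 background genes, 100 samples). A latent-factor
  model rather than a full covariance draw gives exact control of $r$ at
  $O(\text{genes} \times \text{samples})$ cost.
- **Pedigrees.** Monogamous, non-consanguineous families (default three
  generations, three children per couple): one founder carries a single
  causal allele, transmitted to each child with probability 1/2; carriers
  are affected with the set penetrance (0.9 in the study conditions),
  non-carriers with the phenocopy rate (0).
- **Variants.** Every gene receives one common non-functional variant, so
  it is detectable; with probability equal to the qualifying rate (0.05
  base, 0.30 in the enriched module) a gene receives a rare functional
  variant with MAF uniform on $[10^{-4}, 0.04]$ — kept strictly below the
  5% filter so planted truth is unambiguous — placed on the carriers of a
  family in which the dominant rule can accept it. Families whose realized
  affection pattern cannot support segregation (e.g. fewer than 90% of
  carriers affected at penetrance 0.9) are screened out as targets, which
  is what makes planted recall exactly 1 and keeps truth scoring honest.
- **Specificity.** Marker genes are 10-fold enriched in their own cell
  type; all other genes are uniform across types up to ±5% noise.

What the generators deliberately do **not** emulate: linkage
disequilibrium, sequencing error, de novo mutations, count-distribution
artifacts of RNA-seq, or cell-type mixtures within bulk samples. Passing
recovery and calibration tests therefore demonstrates that the statistical
machinery is correct and calibrated under its own model assumptions — not
that real tissues will yield modules of comparable clarity.

Problem sizes in the test and acceptance experiments (450-gene networks,
40 families of ~17 members, 1000-gene burden cohorts, 1000 simulated null
tissues, 10 000 enrichment bootstraps) were chosen as the smallest scales
at which every statistical property under test is comfortably resolvable.

## Numerical and degenerate-input conventions

- Zero-variance genes contribute zero correlation (with a warning) instead
  of propagating `NA`.
- Connectivity ties in gene selection are broken by input order after
  rounding to four decimals, making selection deterministic.
- All-identical connectivities abort the soft-threshold fit (degenerate
  fit) rather than returning a meaningless $R^2$.
- Empirical p-values (permutation and bootstrap) use add-one smoothing and
  are never 0.
- Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage child seeds from the single run seed by hashing the stage name,
  so stage results are reproducible independently of execution order.
  Identical configuration and seed reproduce every output exactly.

## Known limitations

- The dominant-model segregation rule is a deliberate simplification; genes
  following recessive, X-linked, or compound-heterozygous inheritance will
  not be called.
- Burden testing is unadjusted for covariates; confounding by ancestry or
  coverage must be handled upstream (the separate-cohort replication rule
  is the main guard).
- Module detection targets networks up to a few thousand genes in memory;
  blockwise decomposition for much larger gene sets is out of scope.
- At very high soft-threshold powers the absolute overlap scale compresses
  (see above); the permutation validation is the designed safeguard against
  over-interpreting weak branches.
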