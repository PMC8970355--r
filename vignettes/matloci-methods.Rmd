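---
title: "matloci: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{matloci: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
behind each module, the parameters that matter, the numerical conventions,
and the places where a design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The biological setting

Tetrapolar basidiomycetes carry two unlinked mating loci. *MATA* holds
pairs of homeodomain transcription factors (*HD1*/*HD2*) in an alpha and a
beta complex; *MATB* holds pheromone receptors (*STE3.2*, *STE3.4*) and
short pheromone-precursor genes. A cross succeeds only when the partners
differ at both loci, which places the allelic repertoire of each gene
under negative frequency-dependent (balancing) selection. Alleles are
maintained for so long that their coalescence predates speciation:
sister species share allelic lineages (trans-species polymorphism), and
gene trees of mating genes mix the two species in deep clades.

The expected genomic signatures at such loci, relative to a neutral
background of single-copy orthologs, are: within-species diversity
$\pi$ approaching between-species divergence $d_{xy}$; low or negative
Hudson's $F_{ST} = 1 - \bar\pi / d_{xy}$; positive Tajima's D
(intermediate-frequency alleles); elevated synonymous divergence dS among
alleles within a species, with within-species and between-species
pairwise dS of similar magnitude; and an excess of polymorphism relative
to divergence in a multilocus HKA test.

## 2. The synthetic-data generator

The simulator is first-class, tested code: it defines the study
conditions under which every distributional claim in the test suite is
evaluated.

**Time units and rates.** Time is measured in units of $2N$ generations.
Within a population, each pair of lineages coalesces independently at
rate 1 (so $j$ lineages coalesce at rate $\binom{j}{2}$). Mutations fall
on a branch of length $t$ as Poisson($\theta/2 \cdot t$), where
$\theta = 4N\mu L$ is the per-locus population mutation rate. Under these
conventions the expected per-site diversity of a single population is
$\theta/L$ and the expected cross-species divergence is
$\theta(T_{split}+1)/L$.

**Neutral loci** (`simulate_neutral_locus()`): a Kingman coalescent runs
within each species until `T_split`, surviving lineages then merge into
one ancestral population. Each mutation hits a uniform site and
substitutes a uniform different base — the model is deliberately
finite-sites, so repeated hits produce homoplasy and the downstream
statistics see realistic saturation; this also biases $\hat\theta$
slightly downward at high $\theta/L$, visible in the parameter-recovery
numbers.

**Codon mode**: the ancestral sequence is assembled from sense codons;
a proposed change is always kept if synonymous, kept with probability
$\omega$ if it changes the amino acid, and always rejected if it creates
a stop codon. This $\omega$-thinning is simpler than rate rescaling and
suffices to make background genes conserved at the protein level
($\omega = 0.2$ for the neutral background, emulating purifying
selection on orthologs) while mating genes retain protein diversity
($\omega = 1$).

**Balanced loci** (`simulate_balanced_locus()`): $k$ founder sequences
diverge from a common ancestor by Binomial($L$, `d_bal`) substitutions
each; every strain of *both* species draws a lineage uniformly at random;
within-lineage variation is added by a neutral coalescent with
`theta_within`, ignoring species labels. The genealogy is emitted as a
star of lineage subtrees with stem length proportional to `d_bal` — an
approximation of the structured coalescent under strong balancing
selection, not a sample from it. It is adequate for the signatures the
analysis targets (shared lineages, species non-monophyly, $\pi \approx
d_{xy}$) but does not model lineage turnover, migration, or recombination
between lineages.

**Study conditions.** The package-wide defaults are `n_A = n_B = 10`
strains per species, `L = 300` bp, $\theta = 5$ per locus
($\pi \approx 0.017$/site), and `T_split = 10`. One species pair has one
split time, so a single `T_split` is used across all simulation studies;
10 coalescent units places the pair firmly in the reciprocal-monophyly
regime, which is the empirical situation the method addresses (a
background of single-copy orthologs that is overwhelmingly reciprocally
monophyletic). Balanced loci use `d_bal = 0.3` (between-lineage protein
identity far below the 86% threshold), `theta_within = 0.5` (within-class
identity near 100%), and `k = 5` lineages for panel-level experiments —
the low end of the 5–28 allelic classes per mating gene that motivate the
method; `k` is swept over {2, 3, 5} where class recovery itself is the
question.

**What passing tests do and do not show.** The generator produces
gap-free, in-frame, correctly oriented alignments with exactly two
species and no recombination, duplication, misassembly or annotation
error. Tests against it validate the estimators and the inference chain,
not robustness to the alignment and curation problems of real data.

**The pheromone fixture** (`plant_pheromone_fixture()`) plants two true
precursor ORFs (one CaaX, one CpaX, on opposite strands, within 5 kb of
an STE3 feature) and four decoys, each violating exactly one filter
(90 bp; 300 bp; 20+ kb away; no motif) in a 50 kb random contig. The
fixture's contract is that the scanner's accepted set equals the planted
truth; since a random background can by chance contain a passing ORF, the
generator verifies the contract after planting and resamples the
background from deterministic sub-seeds until it holds. This is part of
the generator's construction, not a tuning step: the truth list is
correct by verification, whatever the seed.

## 3. Nucleotide statistics

**Missing data.** Two policies coexist deliberately. Segregating sites
$S$ is a column property: columns containing any gap or ambiguity
(`N`/`X`) in any selected strain are removed entirely (complete
deletion), and the mean pairwise difference $\hat k$ that enters
Tajima's D is computed on the same column set, keeping numerator and
denominator consistent. $\pi$ and $d_{xy}$ are pair properties: each pair
is compared on the columns where both members have a residue (pairwise
deletion). Pairs with zero comparable sites are dropped with a warning.

**Tajima's D** uses the standard constants
($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$) and is `NA` at $S = 0$;
$n < 4$ is accepted with a warning because the variance terms are
unstable there.

**Hudson's $F_{ST}$** is $1 - \bar\pi/d_{xy}$, `NA` when $d_{xy} = 0$,
and negative values are reported as computed — truncation would destroy
exactly the low tail the outlier scan needs.

**Nei–Gojobori dS/dN.** The paper-scale analysis this package supports
used a maximum-likelihood codon estimator; `matloci` implements the
Nei–Gojobori (1986) pathway estimator with Jukes–Cantor correction
instead. The choice is deliberate: the estimator is closed-form,
self-contained, and exactly checkable against an independent
path-enumeration oracle, which the test suite does. Synonymous sites per
codon position are the fraction of the three one-step neighbours that are
synonymous (changes to stops count as nonsynonymous, so syn + nonsyn
sites always total 3 per codon); multi-hit codons average over the
orderings of single steps, excluding orderings that pass through a stop
and renormalizing; codon pairs with all paths blocked are skipped with a
warning. The correction is `NA` once $p \ge 3/4$. No
transition/transversion or codon-frequency weighting is applied, so
absolute dS values are not comparable to ML estimates at high divergence
— within this package they are used comparatively (mating vs background
genes), where the ranking is robust.

A caveat discovered in testing and worth stating: the *median* within-
species dS of a balanced locus is only elevated when cross-lineage pairs
are the majority. With $k = 2$ lineages and a skewed draw (e.g. 7:1
within one species), same-lineage pairs dominate and the median is
legitimately ~0. At the study condition $k = 5$ the cross-lineage
fraction is ~80% and the median behaves as expected.

## 4. The multilocus HKA test

Per locus $i$ with $n_i$ focal-species samples, the model is
$E[S_i] = \theta_i L_i a(n_i)$ and $E[D_i] = \theta_i L_i (T+1)$ with
$a(n) = \sum_{j<n} 1/j$ and the population-size ratio $f$ fixed at 1
(a configuration hook is reserved; the symmetric simulations do not need
it). The moment fit solves, per locus,
$S_i + D_i = \theta_i [L_i a(n_i) + L_i (T+1)]$, with $T$ chosen so the
total divergence matches: bisection on the monotone residual, 200 steps,
tolerance $10^{-10}$, with $\hat T = 0$ when the residual at 0 is already
non-negative. The statistic uses
$\mathrm{Var}[S_i] = E[S_i] + (\theta_i L_i)^2 b(n_i)$,
$\mathrm{Var}[D_i] = E[D_i] + (\theta_i L_i)^2$, and
$X^2 = \sum_i \mathrm{partial}_i$ with df $= L - 1$. Loci with zero
fitted variance contribute 0 with a warning. `fit_hka()` returns a
classed `hka_fit` object (print/summary/coef methods); `hka_statistic()`
completes it; `hka_test()` does both.

**The divergence observation.** $D_i$ is the *mean* cross-species
pairwise difference count on the complete-deletion columns — what a
PopGenome-style dxy feeds an HKAdirect-style input table — rather than
the classical single random pair. This reduces the observation's
variance, but the variance formula above is the classical single-pair
one. The two are close only when all cross pairs share a single
ancestral trunk, i.e. when both species have fully coalesced by the
split: exactly the deep-split regime. In shallow splits (roughly
$T_{split} \lesssim 5$ at $n = 10$) incomplete lineage sorting makes the
pair average genuinely less variable than the formula assumes, and the
chi-square test becomes severely conservative (measured null rejection
near 0). At the study condition $T_{split} = 10$ the measured null
rejection at $\alpha = 0.05$ sits in the low-but-calibrated band the
acceptance suite requires. Users applying the test to recently diverged
species pairs should expect conservative p-values.

**Contamination of the fit.** Balanced loci carry per-locus $\theta$
estimates an order of magnitude above the background, so even a few of
them hold a disproportionate share of the divergence weight and pull
$\hat T$ down; in heavily contaminated panels (several high-$\theta$ loci
among tens) this can shrink the balanced loci's own partial
contributions. At the package's panel condition (4 balanced among 104,
deep split) the balanced loci still rank at the top of the partials, but
partial HKA degrades gracefully rather than sharply as contamination
grows — a property of the classical moment fit, not of this
implementation.

## 5. Allelic classes and trees

**AAI.** Identity between two aligned proteins is
$100 \times$ (identical non-gap columns) / (columns where at least one
has a residue): gap-vs-residue is a mismatch, gap-vs-gap columns are
excluded.

**Clustering.** The 86% threshold is applied with single linkage:
strains are in one allelic class iff connected by a chain of pairs at
AAI $\ge$ 86 (the boundary is inclusive; the threshold itself sits in a
wide empirical gap between within-class and between-class identities, so
the boundary convention is immaterial in practice). Single linkage admits
an exact connected-components oracle (the suite checks against igraph)
and matches the fact that empirical classes are tree clades; average
linkage is available behind `linkage = "average"`. Labels are canonical —
numbered by decreasing class size, ties broken by lexicographically
smallest member — so output is invariant to input order; the arbitrary
numbering of any particular empirical catalogue is not reproduced.

**Trees.** NJ runs on $d = (100 - \mathrm{AAI})/100$ via `ape::nj`;
determinism is tested, and NJ on additive distances provably recovers the
generating topology (property-tested on random 6-taxon trees). A class is
concordant with a tree iff its strain set or the complement is a clade of
the unrooted tree (a clade under some rooting). Reciprocal monophyly
roots on an outgroup when one is given; without an outgroup the same
unrooted-bipartition criterion is used — simulated genealogies carry no
outgroup, and "forms one side of a split" is precisely the property that
is invariant to where the root would fall.

## 6. Mating types and compatibility

A complex class is the *joint* (HD1, HD2) pair label, compared as a
tuple, never per gene; whether a strain differing only at one HD gene of
a complex is a distinct specificity in vivo is untested biology, and the
tuple rule simply reports it as distinct. Predicted type counts use free
combinatorics ($n_{MATA} = n_\alpha \times n_\beta$, etc.) — the field's
convention — even though linked HD pairs cannot recombine freely, so
predicted counts are upper bounds on realizable types; observed distinct
tuples are reported alongside. A component that is *never* observed in a
data set (e.g. the beta complex when both bHD genes are missing from a
panel) is treated as an absent locus and skipped from the product rather
than zeroing it.

Compatibility requires a present-and-unequal difference at one HD complex
*and* one receptor; when the decision hinges on a missing component the
verdict is `indeterminate` rather than a guess. Self-crosses are
`incompatible`, not errors. Inter-species crosses evaluate the same rule
but carry a cautionary note: genotypic compatibility is necessary, not
sufficient, across species, where pre-zygotic barriers act.

Parental unfolding reports, per gene, the set of distinct classes among
sibling monokaryons of one specimen; more than two violates the
single-dikaryon origin and is an error; completeness requires two
distinct classes seen on the MATA side and on the MATB side, which fewer
than two siblings can never establish.

## 7. Pheromone scanning

ORFs are every ATG-to-stop on both strands under the standard code with
length, *including* the stop codon, in [100, 200] bp inclusive (nested
in-frame ORFs are reported independently). The motif test reads the last
four residues: C + two aliphatic ({A, V, L, I}; M excluded) + any =
CaaX; C + polar ({T} by default, configurable) + aliphatic + any = CpaX.
The maturation site is the *rightmost* ER or DR dipeptide strictly
upstream of the motif cysteine, and the mature peptide runs from the
residue after that R through the cysteine inclusive — the alternative
N-terminal boundary (including the E/D) is a documented flag candidate
but not implemented. Proximity uses the minimum interval gap to any STE3
feature on the same contig, default ceiling 5000 bp: large enough to span
gaps inside a ~30 kb *MATB* region, small enough to exclude unlinked
ORFs; mature peptides outside 8–15 aa are accepted with a warning flag
(the empirical 10–11 aa is approximate). Output is sorted by
(contig, start, strand) and strand-symmetric under reverse complement.

## 8. The outlier scan

For each statistic column, the flagged tail contains the
$\lceil q \cdot m \rceil$ most extreme non-missing values among $m$ genes
(upper tail for π/d<sub>xy</sub>, Tajima's D, dS and partial HKA; lower
tail for F<sub>ST</sub>), with the threshold at the adjacent order
statistic and ties at the threshold *not* flagged. The ceiling form is
the natural reading of "the 1% most extreme genes" for panels where
$q \cdot m$ is fractional; with 200 genes it flags exactly the top 2.
Per-species columns of one family (π/d<sub>xy</sub>, Tajima's D, dS) are
flagged on their own tails, and `n_flags` counts flagged columns; a gene
is a candidate at `n_flags >= min_flags` (default 2). dN is reported but
not in the default flag set. The percentile background is all genes,
mating genes included — outliers are defined against the genome, not
against a curated neutral set (a background restricted to one category is
a one-line filter upstream). `NA` is never flagged; all-missing columns
are skipped with a warning.

## 9. Problem sizes and runtime

The test suite and acceptance script size their simulation studies as:
1000 replicates for the single-population Tajima's D equilibrium; 500
panels of 10 loci for HKA null calibration; 200 panels of 20 loci for
parameter recovery; 102 balanced loci (34 per $k \in \{2,3,5\}$) for
class recovery; 200 + 200 loci for monophyly rates; one 104-gene panel
for the end-to-end scan. These sizes put Monte-Carlo error comfortably
inside the acceptance bands while keeping a full run in minutes on one
core.

## 10. Known limitations

- The simulator omits recombination within loci, migration, selection
  beyond $\omega$-thinning, and structured-coalescent genealogies for
  balanced loci; its balanced genealogy is a star approximation.
- The NG86 estimator underestimates dS at saturation relative to ML
  codon models; use it comparatively.
- The HKA chi-square is conservative for shallow species splits (see §4)
  and its moment fit degrades under heavy high-$\theta$ contamination.
- Alignment trimming is assumed already done; the package never edits
  alignments.
- Homology-based rescue of pheromone precursors missed by the motif scan
  (using conserved relatives within a receptor clade) is a future hook,
  not implemented.
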