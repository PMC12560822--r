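---
title: "Detecting convergent amino acid substitutions with a calibrated null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent amino acid substitutions with a calibrated null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convsites)
```

## The problem

Lineages that independently colonize the same extreme niche — the
motivating system is rock-inhabiting fungi, which arose separately within
the Dothideomycetes and Eurotiomycetes — sometimes fix the same amino
acid at the same position of the same protein. A scan for such sites has
to answer two questions: *where* did independent substitutions end in one
derived residue, and *is that surprising* given how fast the gene evolves
and how exchangeable the residues involved are? `convsites` answers both
within a single model, so the observed count and its null expectation are
always computed on the same reconstruction.

## Model and reconstruction

Each gene is modelled by a reversible 20-state Markov process assembled
from the Jones–Taylor–Thornton exchangeabilities (shipped as a plain-text
PAML-dialect file, `inst/extdata/jtt_paml.dat`) and gene-specific
equilibrium frequencies estimated from the gene's own alignment — the
"JTT + f~gene~" combination. The generator is

$$Q_{ab} = s_{ab}\,\pi_b \;(a \neq b), \qquad
  Q_{aa} = -\sum_{b \neq a} Q_{ab},$$

rescaled so $-\sum_a \pi_a Q_{aa} = 1$, i.e. branch lengths are expected
substitutions per site. Because $Q$ is reversible, $D Q D^{-1}$ with
$D = \mathrm{diag}(\sqrt{\pi})$ is symmetric; one eigendecomposition per
gene yields $P(t) = e^{Qt}$ for every branch as two dense
$20 \times 20$ products. The tests cross-check this spectral route
against an independent scaling-and-squaring matrix exponential to
$10^{-8}$, and assert reversibility ($\pi_a P_{ab} = \pi_b P_{ba}$) and
the Chapman–Kolmogorov property.

Ancestral states are *marginal* reconstructions: a postorder (pruning)
pass with per-site rescaling against underflow, then a preorder pass
combining each node's below- and outside-likelihoods. The assigned state
is the posterior argmax, with ties broken toward the lower alphabet index
for determinism. On quartet trees the posteriors are verified to
$10^{-8}$ against brute-force enumeration of all $20^3$ internal-state
assignments. Marginal (rather than joint) reconstruction is the variant
that convergence scans conventionally consume, and the per-node posterior
is exactly the quantity the null expectation needs.

Gaps and `X` are missing data throughout: a missing leaf contributes an
uninformative likelihood vector, a branch with a missing endpoint yields
no substitution call, and a site where all leaves below a node are
missing is flagged and excluded from both the observed and the expected
count at affected branches.

## The convergence statistic

Foreground branches are designated by taxon labels — one label for a
terminal branch, several for the branch above their MRCA. Designations
must be pairwise non-nested, since convergence is only meaningful across
independent lineages. In the default `all_foreground` mode a site counts
as convergent when **every** foreground branch substitutes (assigned
parent state differs from the child's observed or assigned state), all
branches end in one identical derived residue, and every extant
foreground leaf carries that residue — gaps fail this identity
requirement, because the criterion is a statement about extant sequences.
Sites are classed `parallel`, `convergent`, or `mixed` by their ancestral
states; all three count. A `pairwise` mode applies the same rules to each
branch pair and deduplicates sites, for designs where requiring all
lineages simultaneously is too strict; reports always state the mode, and
the run summary gives both the per-site and per-branch-event tallies.

The null expectation for gene $g$ uses the same reconstruction: for
branch $b = (u \to c)$ of length $t_b$,

$$m_b(a \mid s) = \sum_{x \neq a} \mathrm{post}_u(x \mid s)\,
  P_{xa}(t_b), \qquad
  \lambda_g = \sum_s \sum_a \prod_{b} m_b(a \mid s).$$

Using the parent's full posterior rather than its point assignment keeps
$\lambda_g$ honest about reconstruction uncertainty; the discrete site
calls use point assignments so that reported sites are auditable. (Which
of the two the original formulation intended is not stated; this choice
is ours and is recorded here.) The per-gene p-value is the Poisson
exceedance $\Pr(X \ge k_g \mid \lambda_g)$ — 1 when $k_g = 0$, and 0 with
a degenerate-null warning when $\lambda_g = 0 < k_g$ — followed by
Benjamini–Hochberg adjustment across **all** scanned genes (genes with
$k_g = 0$ enter the family at $p = 1$), with candidates reported at
$q < 0.05$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `pseudocount` | 1 | Added to each residue count in f~gene~; keeps all 20 states reachable so $\lambda_g$ is finite and positive even for residues absent from the gene. |
| `mode` | `all_foreground` | Site must substitute on every foreground branch; `pairwise` relaxes to branch pairs. |
| `q_threshold` | 0.05 | FDR bound for the significant-genes table. |
| `min posterior` | 0 (report only) | Substitution calls carry their parent/child posteriors; filtering is left to the user because the significance filter is the Poisson test, not a posterior cutoff. |

## The synthetic benchmark

The simulator draws each site's root state from $\pi$ (stationarity,
consistent with the reversible null), propagates it down every branch
with the model's own $P(t)$, and assembles leaf rows into alignments;
the full internal history is retained so tests can compare
reconstructions against truth. Per-gene frequencies are drawn from a
Dirichlet with concentration $50\,\pi_{\mathrm{JTT}}$ — moderate,
realistic among-gene compositional variation with every residue
represented. Single-branch transition frequencies and leaf composition
are verified against $P(t)$ rows and $\pi$ within three binomial
standard errors.

Injected positives are planted directly on the leaves (and the true
states) of every foreground subtree at chosen sites, with a derived
residue required to differ from each foreground branch's true parent
state — exact, auditable positives rather than a biased simulator. The
derived residue is drawn with probability proportional to its JTT
equilibrium frequency: observed adaptive convergence lands on common
residues, and uniform draws would over-represent rare ones (tryptophan,
cysteine) whose repeated independent gain is close to undetectable in
principle (see *Limitations*).

The default fixture tree has 9 leaves — a clade containing a foreground
cherry, a clade containing two independent foreground terminals, and an
outgroup — mirroring a two-class-plus-outgroup study design with three
foreground targets (one MRCA branch, two terminal branches). Branch
lengths are 0.05–0.15 substitutions/site, chosen once from a likelihood
argument: foreground branches sit at the long end so independent gains
are probable, while background and internal branches are short so the
rival explanation of a shared derived residue — a single deep origin
followed by reversals on several background branches — is strongly
disfavoured and reconstruction stays informative. Keeping foreground
branches moderate rather than maximal also keeps $\lambda_g$ small
(about 0.03–0.05 per 300-site gene), so a handful of genuine convergent
sites is decisive.

What the generator does *not* emulate: insertions/deletions and
alignment error, among-site rate variation, selection on the background,
compositional drift across lineages, and orthology mistakes. Passing
calibration and recovery tests therefore demonstrates internal
consistency of the method under its own model class, not robustness to
every property of real ortholog data.

## Numerical choices

* Per-site likelihood columns are rescaled by their maximum during the
  postorder pass; log-scalings accumulate per site, so deep trees cannot
  underflow. A site whose column becomes all-zero (impossible data)
  yields `-Inf` log-likelihood rather than an error.
* `P(t)` entries below $-10^{-12}$ raise an error; smaller negative
  rounding is clipped to 0 and rows renormalised.
* Posterior argmax ties break toward the lower index in the fixed
  alphabet order `A R N D C Q E G H I L K M F P S T W Y V`.
* All reported positions are 1-based alignment columns.
* Rounding conventions in the genome-features module: densities half-up
  to integers, percentages half-up to 2 decimals, Mb means/SDs half-up
  to 2 decimals, Mb range endpoints truncated to 1 decimal (the printed
  convention for assembly sizes). The Wilcoxon contrast enumerates exact
  p-values when both groups have $\le 10$ tie-free observations and
  otherwise uses the normal approximation with continuity and tie
  corrections, recording which path was taken.

## Problem sizes in the test suite

Unit tests run on quartets and the 9-leaf fixture; the calibration and
recovery experiments use 200 genes of 300 sites each (one null set, one
with 5 injected genes at 3 sites each), sizes at which the full scan
completes in seconds yet Monte-Carlo standard errors are small enough
for three-sigma comparisons. The null experiment checks that the mean
observed convergent-site count matches the mean analytic $\lambda_g$
within three Monte-Carlo standard errors and that at most one gene in
200 reaches $q < 0.05$; the recovery experiment requires at least 90% of
injected genes at $q < 0.05$ with zero false positives.

## Limitations

* **Absorption of convergence into the ancestor.** When the derived
  residue is highly exchangeable with a common ancestral one (D↔N, I↔T,
  L↔M), or the background context at the site is itself variable, the
  likelihood can prefer a single deep origin of the derived residue with
  reversals over several independent gains — detailed balance makes each
  independent gain pay the derived residue's equilibrium frequency, but
  a deep origin pays it only once. The foreground parents are then
  assigned the derived state and the site yields no calls. This is
  intrinsic to reconstruction-based scans, affects rare derived residues
  most, and is the dominant failure mode in recovery experiments; it
  implies the scan's sensitivity is conservative for exactly the
  substitutions that are hardest to distinguish from shared ancestry.
* No among-site rate variation: the underlying formulation names only
  gene-specific frequencies, not a gamma model, so none is fitted;
  fast-evolving sites are consequently somewhat under-expected under the
  null.
* Branch lengths are trusted inputs; they are not re-optimised per gene.
* The per-site null treats sites as independent and ignores epistasis.
* `pairwise` mode sums expectations over pairs, which over-counts the
  union event slightly; with the small per-pair probabilities involved
  the effect is negligible, but the mode is reported with the results.
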