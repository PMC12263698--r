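---
title: "cloneflow: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cloneflow: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

cloneflow reconstructs the evolutionary history of a single patient's tumor
from bulk DNA sequencing read counts: clone genotypes and frequencies, a
clone phylogeny, a mutational tree with driver timing, branch-specific
mutational signatures, a metastatic cell-migration graph, and a
clone-composition sample tree. This vignette is the package's own account of
the underlying models, the tunable parameters, and the choices made where
the design was genuinely open.

## The deconvolution model

Bulk sequencing of a tumor sample observes an aggregate over cell
populations. For SNV $j$ in sample $s$ the observed variant allele
frequency is $V_{js} = \mathrm{alt}_{js} / (\mathrm{alt}_{js} +
\mathrm{ref}_{js})$. cloneflow assumes SNVs are heterozygous in diploid,
copy-number-neutral regions, so a clone carrying SNV $j$ contributes half
its cancer-cell fraction to the VAF:

$$ V \approx \tfrac{1}{2}\, M^{\top} f, \qquad
   M \in \{0,1\}^{K \times J},\; f \ge 0,\; \textstyle\sum_k f_{sk} \le 1 . $$

$M$ is the binary clone-genotype matrix, $f$ the per-sample clone
frequencies (cancer-cell fractions), and $1 - \sum_k f_{sk}$ the
normal-cell fraction. Copy-number-altered regions violate the factor
$\tfrac12$ and are out of scope.

### The search

The factorization is recovered iteratively:

1. **Seeding.** Each sample is binarized per SNV (present when
   $\mathrm{alt} \ge 3$ *and* a one-sided binomial test against a
   sequencing-error rate of $10^{-3}$ gives $p < 0.01$). Each sample's
   presence pattern is a candidate genotype; duplicates are merged. When a
   sample mixes clones from one lineage path, its pattern *is* the deepest
   clone's genotype; cross-lineage mixtures produce union artifacts that
   later steps remove.
2. **Ancestral candidates.** A maximum-parsimony phylogeny over the
   candidates (plus an all-zero germline outgroup) is built and the
   reconstructed ancestral genotypes join the candidate set.
3. **Frequency estimation.** Per sample, $f$ solves a depth-weighted
   least-squares problem under $f \ge 0$, $\sum f \le 1$ (active-set NNLS;
   the sum constraint enters through a slack variable and a penalty row, and
   a ridge of $10^{-8}$ makes the minimum-norm solution the deterministic
   tie-break for rank-deficient systems).
4. **Splitting.** Within one clone's SNV set in one sample, a 1- versus
   2-mean model comparison (BIC, clusters at least 0.04 VAF apart) can
   split a union candidate into a tree-compatible ancestor/descendant pair.
5. **Pruning and refinement.** Clones below the presence threshold
   (`presence_threshold = 0.02`, under typical bulk detection resolution)
   everywhere are dropped. After convergence (stable genotype set, or
   `max_iter = 10`), clones are pruned by a BIC rule on the binomial
   goodness-of-fit statistic (removing a clone frees one frequency
   parameter per sample and must not raise the chi-square by more than
   $n_{\text{samples}} \log n_{\text{entries}}$), and genotypes are
   refined per SNV by exhaustive minimization of the same statistic over
   all $2^K$ assignment columns (skipped above $K = 12$; ties keep the
   current column). An iteration is accepted only if the depth-weighted
   residual does not increase.

The procedure is deterministic: clones are ordered by (mutation count,
lexicographic genotype) and named `Clone1..K`.

## Clone phylogeny and mutational tree

The phylogeny is a rooted tree whose tips are the inferred clones plus an
explicit all-zero germline outgroup; the root genotype is forced to zero.
Topologies are scored by small parsimony on binary characters (unit-cost
Sankoff, identical to Fitch on binary trees but exact at polytomies and at
the degree-2 germline root). Up to 7 clones every rooted topology is scored
exhaustively (10,395 topologies at 7); ties break on the lexicographically
smallest canonical Newick. Beyond 7 clones deterministic stepwise addition
is followed by NNI hill climbing — a local optimum only, which is why the
exhaustive regime is kept as large as is still instant.

Ancestral genotypes resolve ties toward the parent's state (a DELTRAN-like,
changes-late convention: mutations arise and rarely revert), so the implied
changes always sum to the parsimony score. An SNV maps to a branch exactly
where its reconstructed state changes; with homoplasy an SNV can map to
several branches. Contracting zero-mutation branches yields the mutational
tree: one node per mutation group, preorder-numbered `G1..Gn`; drivers are
placed on the group containing their SNV.

## Branch signatures

Each group's mutations are tallied into the 96 pyrimidine-centered SBS
channels (standard COSMIC order; purine-reference mutations are
reverse-complemented). Activities $a$ of catalog signatures $C$ are
estimated by minimizing $\lVert C a - s\rVert^2$ on the probability simplex,
where $s$ is the normalized spectrum — normalized, so activities read as
fractions. Spurious signatures are removed by backward elimination: drop the
lowest-activity signature while the reconstruction cosine stays within
`epsilon_cos = 0.01` of the full fit. Neither threshold is prescribed by the
refitting literature this mirrors; 0.01 is small enough to drop only
negligible contributors. A single harmonization sweep then removes a
signature retained on one branch but on neither its parent nor any child
when its activity is below `isolation_threshold = 0.10` — gains and losses
of mutational processes along a tumor's history are rare, so isolated weak
calls are most likely refitting noise. Branches with fewer than
`min_branch_mutations = 20` mutations cannot support branch-specific
identification; they inherit the parent's retained set and are flagged
`low_confidence`.

Near-collinear catalog columns (e.g. a flat signature next to one sharing
its dominant channels) are genuinely unidentifiable from refitting alone;
retained sets then flip between such columns across branches. cloneflow
surfaces `fit_cosine` and the per-branch spectra precisely so that this
confounding is visible to the user; it does not attempt to resolve it.

## Migration inference

Each clone tip is expanded with one zero-length leaf per sample in which the
clone exceeds the presence threshold, labeled with that sample's anatomical
site. A clone observed at exactly one site has its tip clamped to that site
— the sampled cells *are* the clone. Without this, placing the migration on
the zero-length observation branch ties with the real branch and the
tie-break systematically strips mutation support from migrations. Clones
spanning several sites keep a free tip, which is how zero-mutation
migrations (clone spread without new mutations) arise.

Sites follow a pairwise tree model: a branch whose endpoints agree has
weight 1, a disagreeing branch weight `p_mig` (default 0.1, exposed in the
configuration; the upstream literature does not state a prior, so this is
the package's explicit model). Marginal posteriors at every node come from
exact two-pass sum-product; the migration graph derives from the
max-product MAP labeling with ties broken in input site order and reported
as ambiguous. As `p_mig` goes to 0 the MAP migration count converges to the
Sankoff minimum-migration count. Edges are annotated with the mutation
count of their phylogeny branch; zero-count edges are kept but flagged —
they carry little directional information and deserve skepticism. The
"Primary" pseudo-node attaches to every site holding more than 0.3 of the
root posterior; more than one such site is flagged as a multimodal origin.

## Sample tree

Between-sample distances use abundance-weighted UniFrac on the clone
phylogeny,
$d = \sum_b L_b |p_A(b) - p_B(b)| \,/\, \sum_b L_b (p_A(b) + p_B(b))$,
with clone frequencies renormalized over clones so that distances reflect
tumor composition, not purity; branch lengths are mutation counts. MNTD
(symmetrized mean nearest-taxon patristic distance on presence sets) is
written alongside. The sample tree is built from the UniFrac matrix — the
abundance-aware metric matches the intent of a clone-composition tree; the
choice of metric feeding neighbor joining was left open upstream. Neighbor
joining is the standard Saitou–Nei agglomeration; Q-ties break at the
lowest index pair and negative branch lengths are clamped to zero with a
warning. Samples clustering together plausibly exchange clones, but the
tree can mislead under multi-source seeding; no correction is attempted.

## The simulator: what a green test establishes

`simulate_patient()` generates the world the tests assume: a Yule-shaped
clone tree; per-branch mutation counts (multinomial around equal shares,
minimum 2); mutation channels drawn from per-branch signature mixtures with
random strand; binomial read counts at Poisson-distributed depth around the
target coverage under $V = \tfrac12 M^\top f$; and a random subset of SNVs
labeled drivers. Defaults (5 clones, 6 samples, 3 sites, 200 SNVs, depth
1000) are the scale at which the recovery properties are asserted.

Two aspects deserve emphasis because they bound what the tests establish:

* **Compositions are sparse, site-consistent, and resident-dominated.**
  Every clone is the dominant ("resident") clone of at least one sample;
  co-occurring clones must live at the same anatomical site and ancestors
  of the resident are preferred — the locally-spreading, many-zeros
  pattern seen in real multi-region data. Purity is $1 - U(0.1, 0.5)$.
  Real datasets with heavily admixed cross-lineage samples are harder than
  this world, and deconvolution accuracy there is not covered by these
  tests.
* **Migration histories are identifiable by construction.** Seeding is
  single-source (each non-origin site colonized exactly once), every seeded
  site retains at least one clone tip (an unsampled site could never enter
  an analysis), and histories whose tip sites admit more than one
  minimum-migration labeling are redrawn. Ambiguous histories — symmetric
  roots, back-migrations — are not recoverable by *any* method; on real
  data cloneflow signals such ambiguity through the per-node posteriors and
  the `ambiguous`/`multimodal_origin` flags rather than resolving it.

The generator does not model copy-number alterations, sequencing error
beyond the binomial, multi-allelic sites, or tumor-in-normal contamination.

## Numerical choices

* Constrained least squares uses a hand-rolled Lawson–Hanson active-set
  NNLS (no QP package is available in the target environment); equality
  constraints enter via a penalty row ($\lambda = 10^4$–$10^5$) and
  degenerate minimizers are tie-broken by a tiny ridge ($10^{-8}$
  frequencies, $10^{-12}$ activities). Noiseless mixtures are recovered to
  well under $10^{-6}$.
* Sum-product messages are max-normalized per node; entries are bounded
  below by `p_mig` > 0 so no division by zero occurs, and marginals match
  exhaustive enumeration to $10^{-12}$ on small trees.
* All tie-breaks (clone naming, topology ties, MAP sites, NJ joins) are
  deterministic, which is what makes byte-identical reruns possible.

## Known limitations

Copy-number alterations are unsupported and violate the VAF model. No
bootstrap or other confidence estimates are attached to the phylogeny or
the migration graph. The MP search above 7 clones is a local optimum. The
spurious-signature filter inherits the unidentifiability of collinear
catalogs. Partial pipeline runs (e.g. skipping migration) are not offered.
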