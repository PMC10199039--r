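---
title: "Detecting a shared WGD under lineage-specific rediploidization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a shared WGD under lineage-specific rediploidization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lorescan)
```

## The inference problem

After an autopolyploid whole-genome duplication (WGD), the four allelic
copies at each locus keep recombining until rediploidization suppresses
recombination and resolves them into two diverging ohnolog loci. Because
rediploidization proceeds block by block over tens of millions of years, a
speciation that falls inside this window splits the genome into two
cohorts: loci that rediploidized **before** the split share one duplication
node ancestral to both daughter lineages, while loci that rediploidized
**after** the split resolved independently in each lineage and show two
younger, lineage-specific duplication nodes. A genome-scale census of
ohnolog-pair gene trees that finds *both* cohorts at high frequency is the
signature of a single shared WGD masked by lineage-specific
rediploidization — as opposed to either two independent WGDs or a shared
WGD with fully ancestral resolution.

`lorescan` implements this census and its controls for two focal sister
species (by default tagged `Sturgeon` and `Paddlefish`, the classic
acipenseriform case) embedded in a set of outgroups.

## The topology catalogue

The unit of inference is the rooted four-tip subtree containing the two
ohnologs of each focal species. A rooted, binary, leaf-labelled four-taxon
tree has 15 possible topologies (`enumerate_rooted_topologies()`, the
double factorial $(2n-3)!!$). `classify_rooted_quartet()` maps each one to:

* **PostSpec** — the balanced tree with two same-species cherries
  (independent duplications after speciation): 1 of 15;
* **PreSpec** — balanced with two mixed-species cherries (one shared
  duplication before speciation): 2 of 15;
* **Other** — the 12 caterpillar shapes, one branch move away from a main
  topology.

The paired categories `PostSpecLike`/`PreSpecLike` subdivide 'Other' by the
caterpillar's single cherry (same-species vs mixed). This rule is our
design choice: it is the unique total rule consistent with the unrooted
reduction, because unrooting a caterpillar leaves exactly the central
split implied by its cherry, so every 'Other' tree is one NNI away from
the main topology of its type. It yields 4 PostSpec-like and 8
PreSpec-like topologies. Unrooted, only three quartet topologies exist
(one PostSpec-type, two PreSpec-type), and for families where the second
species retains a single copy, the three rooted triplets split 1:2 the
same way.

Topology identity is computed on leaf-label partitions (cherries and
splits), never on Newick strings, so the classification is invariant to
rotation and tip order. Polytomies are reported as a distinct
`"unresolved"` outcome, kept out of category totals.

## From raw gene trees to classified quartets

`classify_families()` applies, per family: rooting on the most distantly
related sequence (`root_by_most_distant_outgroup()`, using a rank order
derived from the species tree; ties among equally ranked species are
broken by the lexicographically smallest gene identifier — the tie-break
had to be fixed somewhere and this one is reproducible), a clan check
(`is_clan()`; monophyly in the unrooted sense), subtree extraction, and
classification. `apply_family_filters()` implements the dataset inclusion
rules — both ohnologs of a species on different, placed chromosomes; an
outgroup present; the quartet a clan; exactly two copies per focal
species — with independent reason codes so exclusions are auditable.
`extract_phog_quartet()` reproduces the orthogroup post-processing that
maximizes outgroup content while excluding extra focal-species paralogs;
reconciliation (`reconcile()`) uses the strict LCA rule: a node is a
duplication if and only if its children's species sets intersect.

Branch support enters as the two internal-edge supports of the rooted
quartet subtree (the only two supports interior to it). A family is
retained at cut-off $c$ iff $\min(s_1, s_2) \ge c$; missing supports are
conservatively treated as 0 and flagged. `cutoff_sweep()` tabulates
counts, percentages and fold deviations from the uniform-topology null
(expected frequencies 1/15, 2/15, 12/15) across cut-offs 0–100 by 5. A
strong WGD signal shows both PreSpec and PostSpec far above 1 while
'Other' collapses with stringency.

## The AU test

To ask whether a family's alignment can *decisively* distinguish the
quartet topologies, `au_quartet()` computes per-site log-likelihoods of
the three unrooted topologies under the JTT model with four
equal-probability discrete-gamma categories (the model family used for the
upstream tree inference) and runs the Approximately Unbiased test by
multiscale RELL bootstrap: resamples of $\lceil rL \rceil$ sites at scales
$r \in \{0.5, \dots, 1.4\}$ (ten scales, $B$ replicates each; defaults
follow common AU practice since upstream tools do not print theirs), a
probit-transformed fit $z(r) = d\sqrt{r} + c/\sqrt{r}$ by weighted least
squares over scales with proportions inside $(0,1)$, and
$p_{AU} = 1 - \Phi(d - c)$. Degenerate proportions map to $p \in \{0,1\}$;
ties among topologies are split fractionally so identical site-likelihood
vectors receive identical p-values.

Numerical choices: the five branch lengths are re-optimized per candidate
topology by coordinate-wise bounded scalar optimization (two sweeps, lower
bound $10^{-6}$) — re-optimizing rather than reusing estimates is the
conservative option for a 4-taxon tree, and cheap. The gamma shape is
estimated once by 1-D optimization on the provisionally best topology and
reused, since a quartet alignment carries little information to estimate
it thrice. The pruning likelihood is validated in the test suite both
against exhaustive summation over internal-node states and against an
independent likelihood implementation. Site patterns are compressed before
optimization; all-gap columns are skipped and recorded.

## Ks distributions

Synonymous distances corroborate the two-cohort structure on an axis
independent of topology. `ks_ng86()` is a counting (NG86) estimator with
Jukes–Cantor correction: site counts averaged over the two sequences,
multi-hit codons averaged over minimal substitution pathways
(stop-crossing pathways excluded when avoidable; changes to stops counted
as nonsynonymous), proportions $\ge 3/4$ flagged non-computable. We chose
a counting estimator over a codon-ML pipeline deliberately: the claim
being reproduced is the *ordering* of category distributions (PostSpec
peak < ortholog peak < PreSpec peak, with the '-like' categories
intermediate), which is insensitive to the estimator family; absolute Ks
values will differ slightly from ML estimates.

`build_ks_datasets()` enforces the accounting rules: per classified family
one intra-species pair per species; each PreSpec family additionally
contributes exactly two inter-species ortholog pairs (its two mixed
cherries), whose divergence matches the speciation; flagged pairs are
removed and records with $K_s \ge 0.3$ are excluded from summaries.
Quartiles use linear interpolation; densities use a Gaussian kernel with
Silverman's bandwidth on a fixed 512-point grid over $[0, 0.3]$ for
reproducibility. `bimodality_check()` finds density modes by topographic
prominence — under strict support filtering the pooled ohnolog
distribution should resolve into the two rediploidization cohorts.

## Synteny and read depth

Rediploidization is a regional process, so neighbouring genes should share
divergence cohorts. `build_links()` lays classified pairs onto
chromosomes (intra-species ohnolog links, inter-species ortholog links for
PreSpec, or the combined view), `detect_blocks()` calls maximal
same-category runs per chromosome pair (defaults `min_genes = 3`,
`max_gap = 1`; the source analyses draw circos plots without printing a
block-calling rule, so these are exposed configuration), and
`clustering_permutation_test()` turns the qualitative claim "categories
are not randomly distributed" into a permutation p-value on the number of
adjacent same-category pairs.

Collapsed duplicate regions — two loci assembled as one — carry the reads
of both and sit at twice the single-copy depth. `coverage_analysis()`
estimates the reference mode from two-copy ohnolog genes and calls a gene
`double` above `threshold_factor` (default 1.5, the midpoint of the 1x and
2x expectations; the source identifies the double peak visually and prints
no cut-off) times that mode. Read mapping itself is upstream; the module
consumes per-gene mean-depth tables.

## Supermatrix preparation

`select_dating_families()` keeps PreSpec families with both supports at
100 that are single-copy in all other species; `shuffle_concat()` builds
replicate concatenations in which a seeded fair coin assigns each family's
two ohnolog units as the A or B copy (five replicates by default),
recording assignments and exact partition boundaries;
`trim_gapped_columns()` applies no-gaps trimming (idempotent, gap-free by
construction). Entropy-based trimming and the Bayesian dating run itself
are out of scope — the package prepares inputs only, so published
trimmed-site counts are not reproducible here and are not asserted.

## The synthetic-data generator

The simulator is first-class, tested code; it is the ground truth for
every other module. Its defaults are the study conditions and are set
once:

* **Times** (Ma): WGD at 250, speciation at 170, outgroup splits at 368
  (neopterygian analogue) and 465 (root), matching the scale of the dated
  acipenseriform scenario. Rediploidization times are Uniform(0, 250) per
  block — the waiting-time law is not empirically constrained, so the
  flattest choice is used — giving an expected 32% PreSpec fraction;
  `prespec_fraction` optionally pins an exact design fraction of blocks
  (assigned exactly and placed randomly) for parameter-recovery
  experiments.
* **Rates**: amino-acid and synonymous rates 5e-4 subst/site/Ma for
  sturgeon, ancestral and outgroup branches, paddlefish 1.2x faster —
  a slowly evolving genome with mild lineage asymmetry. On this scale
  ortholog Ks is about 0.19 and ohnolog Ks spans 0–0.3, straddling the
  0.3 exclusion threshold realistically.
* **Blocks**: 30 blocks of 4–10 families laid out contiguously on 5
  chromosome pairs, collinear across species — block structure is exactly
  what the synteny module must recover.
* **Noise**: one NNI inside the quartet with probability
  `p_nni * exp(-b_min / 0.005)`, so topology errors concentrate in
  families whose internal branches are short (rediploidization close to
  speciation), reproducing the observed enrichment of weakly supported
  'Other' trees near the boundary. Supports are a saturating function
  `100(1 - exp(-b / 0.0015))` of internal branch length plus Gaussian
  noise (sd 1.5) — a deliberate heuristic stand-in for real bootstrap
  replicates, chosen for speed; NNI-affected trees draw supports
  Uniform(40, 90) so they behave like genuinely unstable trees under
  filtering.
* **Observables**: paddlefish ohnolog loss with probability 0.05;
  assembly collapse with probability 0.15 among PostSpec families whose
  paddlefish copy rediploidized in the most recent 35% of the
  post-speciation window (recent pairs are the similar ones); depths
  Normal(30, 10% CV), doubled for collapsed genes.

Sequence evolution uses the package's own reversible-model machinery: the
JTT matrix with discrete-gamma rates for amino acids, and for coding
sequences a 61-state codon chain with synonymous changes at rate 1 and
nonsynonymous at `omega = 0.2`, scaled so one unit of branch length is one
synonymous substitution per (NG86-counted) synonymous site — realized Ks
therefore tracks `2 * syn_rate * divergence_time` by construction, which
the test suite verifies within estimator tolerance.

What the simulator does **not** model: incomplete lineage sorting,
hybridization, gene conversion after resolution, chromosome
rearrangements beyond block placement, indels/alignment error (alignments
are gap-free unless constructed otherwise), and real bootstrap supports.
Passing tests therefore demonstrate internal correctness and recoverable
signal under the stated generative model, not robustness to every process
shaping real genomes.

## Problem sizes and reproducibility

Everything flows from one master seed per run (`simulate_dataset()` uses
sequential draws; `run_pipeline()` threads the seed through every stage),
and outputs are written with fixed formatting so identical inputs give
byte-identical tables. The shipped test suite exercises the pipeline at
desk scale — about 1,000 families for classification-recovery
experiments, 200 replicates for AU-test calibration at alignment length
500, 40-block runs for Ks distribution ordering — sizes chosen so the
whole suite completes in a few minutes while keeping Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* The 'Other' subdivision rule is the natural split-based one, but
  upstream implementations may handle unresolved edge cases differently.
* Average pairwise identity follows the stated gap convention (gap–gap
  positions excluded per pair, single-gap positions counted as
  mismatches); other alignment-statistics tools differ in exactly this
  convention.
* The saturation statistic is reported as the regression slope through
  the origin of uncorrected on patristic distance (1 = unsaturated);
  some tools report `1 - slope`.
* NG86 Ks values are not numerically interchangeable with codon-ML
  estimates; only distribution shapes and orderings should be compared.
* `quartet_subtree()` relies on node-label bookkeeping when re-rooting
  trees supplied from outside; trees already rooted on their outgroup
  (the simulator's output, and the recommended input convention) are
  unaffected.
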