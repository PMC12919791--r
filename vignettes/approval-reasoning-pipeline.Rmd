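---
title: "Methods: the approval-reasoning pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the approval-reasoning pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`molapprove` implements, at desk scale, an interpretable small-molecule
approval-prediction pipeline in which a reasoning policy compares a candidate
molecule's computed descriptors against those of its most similar approved
and unapproved reference compounds, emits a structured
`<think>/<label>/<score>` answer, and is trained with group-relative policy
optimization (GRPO) against a fully verifiable five-component reward. This
vignette is the package's own account of the model, its tunable parameters,
the synthetic data it tests itself on, and the numerical choices made where
the design was genuinely open.

## The pipeline

1. **Dataset** — molecule tables (`id, smiles, label, split`) are
   canonicalized, class-balanced by random undersampling, and partitioned
   8:1:1 with per-class stratification. External sets are deduplicated
   against the internal splits by canonical-SMILES string equality.
2. **Featurization** — eleven physicochemical/structural descriptors plus
   PAINS and Brenk-type structural alerts, the Ghose filter and QED.
3. **Embedding** — a masked mean-pooling contract over token hidden states
   (`sum_t m_t h_t / sum_t m_t`), served by a deterministic mock encoder.
4. **Similarity retrieval** — an XGBoost binary classifier tuned on the
   embeddings; each molecule is mapped to its terminal-leaf-index vector
   (one entry per tree) and the five nearest approved and unapproved
   neighbors under Hamming distance are retrieved.
5. **Prompting** — candidate and neighbor descriptor profiles serialized
   into a deterministic comparative prompt.
6. **GRPO** — the clipped-surrogate, KL-penalized group-relative objective,
   exercised end to end on a toy categorical policy over templated
   completions scored by the real reward suite.
7. **Evaluation** — confusion metrics, rank AUC, checkpoint selection,
   four conventional baselines, drug-likeness comparators, and three
   ablation configurations.

## Descriptor semantics (OpenBabel backend)

All chemistry goes through OpenBabel 3.1.1 (via ChemmineOB/ChemmineR), and
descriptor names mean what that toolkit computes:

* `logp` and `molar_refractivity` are Wildman–Crippen atom-contribution
  estimates; `tpsa` is the Ertl topological polar surface area (Å²);
  `hbd`/`hba` follow OpenBabel's donor/acceptor SMARTS definitions.
* `rotatable_bonds` counts single, acyclic, non-terminal sigma bonds
  excluding triple-bond neighbours (`[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]`). This
  is the classic definition; it does not apply the stricter amide/ester
  exclusions some toolkits use (aspirin counts 3 here, not 2).
* `ring_count` is the smallest-set ring count (bonds − atoms + components);
  `heavy_atoms` excludes hydrogens; `formal_charge` is the net charge read
  from the bracket atoms of the canonical SMILES.
* `chiral_centers` counts potential tetrahedral stereocenters, unassigned
  ones included: carbons with four sigma bonds whose four branches have
  pairwise-distinct blocked-BFS layer signatures. This atom-ranking
  approximation does not resolve para/meso dependencies between centers —
  a deliberate trade against reimplementing full CIP perception.

Internally, molecular properties are computed on the hydrogen-implicit
form while connectivity, ring perception and alert matching run on
explicit-hydrogen structures (the alert catalogs constrain hydrogen
positions, and single-heavy-atom molecules only parse robustly that way).

## Structural alerts and drug-likeness

* **PAINS**: the full 480-pattern combined A+B+C catalog of pan-assay
  interference SMARTS (Baell & Holloway 2010), shipped as plain text and
  matched with OpenBabel SMARTS. A hit count is the number of distinct
  catalog patterns matched.
* **Brenk-type alerts**: the 116 unwanted-functionality SMARTS tabulated in
  the QED publication (Bickerton et al. 2012), which derive from Brenk
  et al. (2008). Two patterns are multi-component (`X.X.X`); OpenBabel
  SMARTS has no component-level conjunction, so they are evaluated as
  match-count thresholds on the single component (≥3 ester groups, ≥4
  fluorines), preserving their meaning. The same catalog supplies the
  ALERTS term of QED, exactly as in the QED definition.
* **Ghose filter**: all four conditions inclusive — molecular weight
  160–480 Da, logP −0.4–5.6, molar refractivity 40–130, total atom count
  (hydrogens included) 20–70.
* **QED**: the weighted-desirability form — each of eight properties (MW,
  ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS) is mapped through its published
  asymmetric-double-sigmoid desirability and combined as the weighted
  geometric mean with the published mean weights. Because the underlying
  descriptor definitions are OpenBabel's, scores differ in the second
  decimal from implementations built on other toolkits. The drug-likeness
  gate is strict: `qed > 0.5`.

## The synthetic fixture generator

Tests and the end-to-end smoke run use molecules drawn from a fixed
grammar: benzene, cyclohexane or pyridine scaffolds bearing 0–4
substituents from a 12-element set (alkyls, hydroxy/methoxy, amino,
halogens, carboxyl/ester, nitrile). Labels are planted by a descriptor
rule — `approved ⇔ TPSA ≥ 30 Å² and logP ≤ 1.9` — with thresholds fixed
once near the grammar's descriptor medians so both classes are well
populated; label noise then flips exactly `round(noise · n)` labels per
class in each direction, keeping class counts exact and making the
label–descriptor agreement equal `1 − noise` by construction (an i.i.d.
flip would leave the realized rate random at small n).

What this emulates: a balanced, canonicalized, deduplicated compound table
whose labels are partially explained by physicochemistry. What it does not
emulate: real structural diversity, activity cliffs, assay noise
correlated with chemistry, or the historical biases of approval decisions.
Green tests therefore certify the machinery — determinism, contracts,
arithmetic, retrieval exactness, trainability — not real-world predictive
performance.

## Mock encoder

The mock backend embeds the canonical SMILES string as a hashed character
2-/3-gram count vector (1024 buckets, polynomial rolling hash) projected
through a fixed seeded Gaussian matrix (seed 760813, recorded in run
manifests) to the configured dimension (default 768) and unit-normalized.
It is deterministic, batching-invariant and cheap; it carries real signal
only insofar as SMILES text reflects structure, which is sufficient for
the retrieval and pipeline tests. A pretrained transformer encoder can be
supplied behind the same `encode(smiles, d)` contract; the package never
downloads weights, and pooling for such encoders is the same masked mean.

## Similarity search

The boosted-tree similarity model is tuned by a compact univariate
tree-structured Parzen estimator: after 10 random startup trials, each
parameter (log-scale learning rate and L1/L2, integer depth, subsampling
ratios) is proposed by splitting completed trials at the best-25% loss
quantile, fitting Gaussian-kernel densities over good and remaining
trials, and taking the best of 24 candidates by density ratio. Trials are
scored by log-loss on a stratified 10% tuning slice held out of the
training data, with boosting grown in rungs of 10 rounds, early-stopped
at 20 stale rounds, and median-pruned against previous trials at the same
rung. The best configuration is refit on the full training set. Desk
default is 25 trials; the reference-scale 1000 remains one parameter away.
Everything runs single-threaded so fitted models are bit-reproducible.

Leaf retrieval is exact: Hamming distance over terminal-leaf index
vectors, ties broken by ascending corpus position (the tie rule the tests'
brute-force oracle shares), with the query's own id excluded in
self-comparison mode.

## Response schema and rewards

Responses are parsed totally (no input raises): first well-formed
`<think>`, `<label>`, `<score>` blocks; labels case-folded and validated
against {approved, unapproved}; scores parsed as decimals and marked
absent — never clamped — outside [0, 1]; all tag open/close counts kept as
diagnostics.

The reward schedule (component maxima sum to 5.75):

| component | values |
|---|---|
| correctness | 2.0 if the parsed label equals truth, else 0.0 |
| XML format | 0.125 per tag present exactly once and in schema order, max 0.75 |
| soft format | 0.5 if all three pairs are internally well-formed, padding and pair reordering tolerated |
| interpretability | 0.5 if the label is semantically valid |
| confidence alignment | correct: ≥0.7→2.0, [0.4,0.7)→1.0, <0.4→0.0; incorrect: <0.4→1.0, [0.4,0.7)→0.5, ≥0.7→0.0 |

Open choices resolved here: a duplicated tag earns nothing for that tag
(singularity is per-tag); the strict XML reward demands schema order while
the soft reward accepts reordered pairs; an absent or unparseable score —
or an invalid label — earns zero alignment reward rather than counting as
low confidence, so format failure is never rewarded. One consequence of
order enforcement worth knowing: a misplaced singular tag also suppresses
the credit of tags it conflicts with, so the clean monotonicity guarantee
is that deleting a *credit-earning* tag lowers the XML reward by exactly
its 0.125 contribution.

## GRPO and the toy policy

For each prompt `s_j`, K completions are sampled, rewarded, and advantaged
against the group mean (`A_jk = R_jk − mean_k R_jk`); the loss is

```
L(θ) = − Σ_j Σ_k min(r_jk A_jk, clip(r_jk, 1−ε, 1+ε) A_jk)
       + β Σ_j D_KL(π_old(·|s_j) ‖ π_θ(·|s_j))
```

with `r_jk = π_θ(a_jk|s_j) / π_old(a_jk|s_j)`. ε and β default to the
conventional 0.2 and 0.04 (they are exposed in the config; the reference
recipe defers them to library defaults). The KL reference is the per-step
snapshot `π_old` itself, exactly as the objective is written — not a
separately frozen initial policy. Two consequences, verified by the
paired-run tests: a very large β bounds *per-step* movement (smaller mean
per-step KL), while total drift from the initial policy is not bounded,
since the reference travels with the policy.

The toy policy is one categorical distribution per prompt over eight
templated completions spanning the reward landscape (ideal; correct at
moderate/low confidence; incorrect at low/high confidence; missing score
block; invalid label; no tags), so every reward component is exercised and
exactly one completion attains 5.75. Sampling honors temperature 1,
top-p 0.9, top-k 9; ratios are computed against the untruncated snapshot,
as trainer implementations do. Updates use AdamW (β₁ 0.9, β₂ 0.99,
decoupled weight decay 0.1), 100 linear warmup steps, cosine decay, and
global gradient-norm clipping at 0.1, with 2 inner iterations per sampled
batch so the clipping and KL terms are actually active. The toy default
learning rate is 0.05 — the policy has a few dozen logits, not billions of
transformer weights, and the recipe's 5e-6 (kept as the config default)
cannot move logits O(5) within the step budget. On the planted task the
EMA of the mean sampled reward reaches ≥95% of the attainable 5.75 within
2000 steps across seeds; late in training the policy plateaus with
`p(best) ≈ 0.88`, the equilibrium between reward pressure, weight decay
and the top-p cutoff.

## Evaluation conventions

* AUC is the rank-based (Mann–Whitney) form with ties counted one half;
  the tests check it against an exhaustive pairwise oracle up to n = 50.
* Turning a label+confidence answer into an approval probability is not
  standardized anywhere; the package's documented convention is `score`
  for approved, `1 − score` for unapproved, and 0.5 when either field
  failed to parse. Unparseable labels count as (wrong) negative
  predictions in the confusion matrix.
* Checkpoint selection gates on complete (100%) format adherence — the
  fraction of completions earning the full strict XML reward — then
  maximizes AUC, breaking ties by F1 and then recency, falling back with
  a warning if no checkpoint fully adheres.
* The four baselines (logistic regression, radial SVM, 5-NN, XGBoost) are
  trained on the 11-descriptor vectors by default; embeddings can be
  passed instead. Descriptors are the default because the
  embeddings-plus-classifier configuration already exists separately as an
  ablation and the two should stay distinguishable.
* Ablations: `no_neighbors` rebuilds prompts without the comparative block
  (and the rule-based responder degrades to its QED fallback);
  `direct_gbt` and `direct_logistic` classify the embeddings directly,
  skipping the reasoning stage entirely, with a boosted-tree ensemble and
  an L2-regularized (λ = 0.01) logistic model respectively.
* In end-to-end runs the role of the reasoning model is played by a
  deterministic rule-based responder (inverse-distance neighbor vote with
  vote share as confidence). It exists so prompts, responses, rewards and
  reports can be exercised without any language model; it makes no claim
  to the reasoning quality of a trained policy.

## Problem sizes and limitations

The test suite runs the retrieval oracle at 50 queries × 200 molecules,
the baseline bench at 400 molecules, reward fuzzing at 10,000
completions, and the end-to-end smoke at 100 molecules per class with 25
search trials and a 600-step toy run — sizes chosen so the whole suite
stays comfortably reproducible on a single CPU.

What is out of scope by design: fine-tuning any transformer policy (the
reference model is an 8-billion-parameter LLM trained for hundreds of GPU
hours), pretrained-encoder weights, external compound databases, and
reproduction of real-data AUC/F1 figures; the desk-scale pipeline
validates the machinery those results rest on, not the results
themselves.
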