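---
title: "Detecting co-authorship in facilitated-communication texts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-authorship in facilitated-communication texts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costylo)
```

## The problem

Facilitated communication (FC) produces text through two hands: a user types
while a facilitator provides physical support. The authorship question —
does the user contribute anything detectable, or is the facilitator the sole
stylistic source? — is an attribution problem that stylometry is well suited
to, because unconscious style markers (function-word frequencies, character
n-gram patterns) are hard to fake and accumulate over large corpora.
`costylo` implements a complete pipeline for this question: session-file
parsing, feature profiling, delta distances, cluster and rank analyses,
pair-relationship statistics, and bootstrap consensus networks, together
with a synthetic corpus generator whose ground truth makes every stage
testable.

The unit of analysis throughout is the *pair text*: the concatenated
user-side output of all sessions of one user–facilitator pairing. In a
multi-facilitator corpus each user contributes several pair texts, one per
facilitator, and the analyses ask whether texts group by user or by
facilitator.

## From transcripts to features

Session transcripts interleave facilitator prompts (typed in caps lock)
with user output. `split_dialogue()` attributes a line to the facilitator
when at least 80% of its alphabetic characters are uppercase — a threshold
rather than an exact all-caps test, so punctuation, digits and accented
capitals do not flip the attribution. Lines without alphabetic characters
cannot carry the marking and default to the user. A mixed-case facilitator
prompt would be mis-assigned under any threshold; this is a limitation of
the caps-lock convention itself, not of the parser.

`tokenize()` lowercases and extracts maximal runs of Unicode letters.
Italian elision is the one genuinely open tokenization choice: we treat the
apostrophe as a boundary with the elided article kept as its own token
(`l'anima` → `l'`, `anima`), which matches common stylometric practice for
Italian and keeps clitics like *l'* as countable function words; a
plain-split dialect (`elision = "split"`) is exposed so replications can
probe sensitivity. Accents are preserved (*sì* ≠ *si*). No culling
(minimum document frequency) is applied.

`extract_features()` builds the most-frequent-feature matrix: the top *k*
features by summed corpus count (ties broken lexicographically, making the
feature order fully deterministic), cell values being relative frequencies
within each sample — counts divided by the sample's full token (or n-gram)
total, so the denominators do not depend on *k*. Character trigrams slide
over the space-joined token stream with spaces included, so word-boundary
patterns count as features. `zscore_matrix()` standardizes each feature
across samples with the *population* standard deviation — the convention
under which Burrows' delta is exactly the mean absolute z-score difference —
and drops zero-variance features, which carry no information and would
divide by zero.

## Distances, clustering and leaf pairing

Two delta metrics are implemented from their definitions:

* cosine delta: \(d(a,b) = 1 - \frac{z_a \cdot z_b}{\lVert z_a\rVert\,\lVert z_b\rVert}\), bounded in \([0, 2]\);
* Burrows (classical) delta: \(d(a,b) = \frac{1}{k}\sum_f |z_{af} - z_{bf}|\).

Cosine delta is the working metric (it is robust to text-length effects on
z-score magnitude, being scale-invariant per sample); Burrows delta is kept
as an independent cross-check. Both are verified against hand-computed
oracles at `1e-10`.

Dendrograms use `stats::hclust` on the delta distances. The linkage is not
dictated by the method, so it is a configurable parameter; the default is
Ward on the distances (`ward.D2`), with `complete` and `average` available.
The *leaf pairing* statistic formalizes "texts of the same user pair at the
leaves": a sample's sibling is its first merge partner when that first
merge is leaf–leaf; samples first absorbed into multi-leaf clusters have no
sibling and count against the rate. This is deliberately strict — it only
credits exact leaf-level pairing.

The chunking design guards the clustering against artefacts of any single
cut: each text is split into four consecutive near-equal quarters
(remainder tokens go to the earliest quarters, so chunk lengths differ by
at most 3 tokens) and recombined three ways (1+2/3+4, 1+3/2+4, 1+4/2+3).
Texts whose chunks would not each exceed the 5,000-word floor are excluded,
and the length filter is a strict inequality: exactly 5,000 words is out.

## The red line and its two nulls

For a focal text whose facilitator produced \(n\) texts, the *facilitator's
line* (red line) sits at rank \(r = n - 1\): if the facilitator were the
sole stylistic source, only the other same-facilitator texts should occupy
the first \(r\) positions of the focal text's neighbour ranking, and
same-user texts (always written with *other* facilitators) should rank
below it. A same-user text at rank \(\le r\) breaches the barrier.
Distance ties are broken by label order, so rankings are deterministic.

Two distinct null models quantify "ranking at random", and they are not
interchangeable:

* **Uniform null** (`null_expected_breaches()`): every column is a
  uniformly random permutation. With \(m\) same-user texts among \(M\)
  neighbours, breaches are hypergeometric with mean \(mr/M\). This is the
  right reference when the distance table carries no structure at all, and
  the permutation-consistency property test verifies the closed form
  against shuffled rankings.
* **Facilitator-conditioned null** (`conditional_null_breaches()`): the
  facilitator-only hypothesis does *not* predict structureless rankings —
  it predicts facilitator-driven rankings in which the user labels are
  meaningless. The correct formalization holds each column's observed
  ranking fixed and treats the same-user flags as exchangeable among the
  cross-facilitator neighbours: with \(C\) cross-facilitator texts of which
  \(B\) rank above the line, breaches are hypergeometric in \((B, C-B, m)\),
  and column draws are summed by Monte Carlo.

The distinction matters in practice. On facilitator-only synthetic corpora
(mixing weight \(\lambda = 0\), below) same-facilitator texts are far
closer to each other than to anything else, so essentially no
cross-facilitator text — and hence no same-user text — rises above the
line: observed breach totals sit near 0, inside the conditional null's
interval but far below the uniform null's expectation (about 10 for the
28-text reference design). Calibration claims about the pipeline are
therefore made against the conditional null; the uniform null is reported
as descriptive context for how far a corpus departs from full
exchangeability.

## Pair-relationship groups and their statistics

Ordered pairs of texts are classified into five groups: `IU` (same user),
`FU` (same facilitator, stylistically similar users), `F` (same facilitator
only), `RU` (similar users only), `NR` (neither). Every ordered pair of the
\(N\) texts contributes one observation (so \(N(N-1)\) in total), matching
the convention of reading each distance-table column independently.

The similarity map (at most two similar users per user) is a configuration
input; the packaged `center2_similarity()` map is directional, and
`assign_relation()` applies it directionally by default — the focal text's
user must list the other text's user. This is a deliberate choice: the map
explicitly notes that not all relationships are mutual, and only the
directional reading makes the group sizes of the reference design come out
as odd numbers (33, 109, 117, 437), which a symmetrized relation over
ordered pairs could never produce. A `symmetric = TRUE` option restores
mutuality for maps intended that way.

Group statistics follow the reference analysis: one-sample t-tests against
the neutral distance 1 (the midpoint of cosine delta's range) and against
the corpus-average distance; and, because group sizes are heavily
unbalanced, iterated equal-size subsample t-tests — both groups subsampled
without replacement to the smaller size, an unpaired two-sample test per
repetition, ten repetitions, mean p reported. The unpaired reading is the
only one consistent with equalizing group sizes by subsampling; there is no
natural pairing between, say, 60 IU and 437 NR distances. No
multiple-testing correction is applied, matching the reference procedure.

Classification (`classify_relations()`) uses the scalar pair distance as
the sole feature — the only quantity the group analysis attaches to an
observation — with stratified 5-fold cross-validation and either a
distance-weighted KNN (implemented here; inverse-distance votes over the
k nearest training values) or an RBF SVM via `e1071`. Accuracies measure
the separability of the groups' distance distributions and are reported
per configuration; they are sensitive to the feature representation, which
richer (multivariate) readings would change.

## Bootstrap consensus networks

`run_bcn()` repeats the feature–z-score–distance analysis across a sweep of
feature-vector sizes (default 100 to 5,000 in steps of 100) and, per run,
adds weight \(w_j = k_{nn} + 1 - j\) to the undirected edge between each
node and its \(j\)-th nearest neighbour (\(k_{nn} = 3\) by default, so
weights 3/2/1). Mutual selections sum. The edge rule and weights are
configuration, since the canonical implementations leave them
package-internal; weight conservation — total accumulated weight is exactly
`runs × nodes × Σ w_j` — holds for every configuration and is asserted
exactly in the tests. Feature matrices are extracted once at the maximum
sweep size and truncated per run, which is equivalent to per-run extraction
because feature order and denominators do not depend on *k*.

`possible_links()` reports theoretical maxima per category. The primary
counts are per-text link *slots* (ordered pairs: a facilitator with \(m\)
texts offers each of them \(m-1\) partners, \(\sum m(m-1)\) in total — 60
same-user, 142 same-facilitator, 554 neither for the 28-text reference
design); unordered pair counts (30/71/277) are given alongside. The ordered
convention is the one under which the three categories and the group counts
add up to \(N(N-1)\).

## The synthetic generator: what it emulates and what it does not

The generator is the ground truth for the whole pipeline. A shared
vocabulary of \(V\) words carries a Zipfian base distribution
\(p_i \propto i^{-s}\); each author (user or facilitator) perturbs it
multiplicatively, \(q_i \propto p_i e^{\sigma \varepsilon_i}\) with
\(\varepsilon_i \sim N(0,1)\), renormalized — so profile divergence scales
smoothly with \(\sigma\), and \(\sigma = 0\) collapses all authors onto the
base. A pair text draws each token independently from the user's profile
with probability \(\lambda\) and from the facilitator's otherwise;
\(\lambda = 0\) realizes the facilitator-only null exactly, \(\lambda = 1\)
a pure user text. Per-token source labels are retained.

Reference conditions, fixed once: \(V = 10^4\), \(s = 1\),
\(\sigma = 0.4\), 20,000 words per pairing, \(\lambda = 0.5\) as the
generator default (an equal-contribution mixture; the analysis scripts use
\(\lambda = 0.6\) for their worked signal corpora). \(\sigma = 0.4\) makes
author log-frequency perturbations comparable to the sampling noise of
mid-frequency words at these text lengths — profiles that are clearly
separable on 1,000-MFW vectors without being caricatures. The two packaged
designs mirror the reference corpora: 7 users × 1 facilitator, and 28
pairings over 10 users × 7 facilitators with users-per-facilitator counts
10/6/4/2/2/1/3.

The model is a unigram mixture: it matches the feature space of the
word-frequency analyses but simulates no syntax, no topic structure, no
session-level drift, and no orthographic idiosyncrasies beyond word choice.
Passing tests on synthetic corpora therefore show that the pipeline's
machinery recovers planted frequency-level signal and is calibrated under
its null; they do not show that real FC texts contain such signal, nor do
they rule out topic or register confounds that a unigram model cannot
express. All randomness flows from one integer seed through R's RNG in a
fixed draw order, and every generated corpus records its seed.

Verified generator properties (all in the test suite): the caps-lock
round trip recovers user token streams exactly; empirical token
frequencies match profiles within multinomial error; same-user leaf
pairing averages ≥ 0.9 at \(\lambda \ge 0.5\) (20 seeds); mean same-user
(IU) distance decreases monotonically in \(\lambda\) over
\(\{0, 0.25, 0.5, 0.75, 1\}\); and facilitator-only (\(\lambda = 0\))
breach totals fall inside the conditional null's central 95% interval in
well over 90% of 50 seeds.

## Numerical choices and degenerate inputs

* Ties: feature ranks and distance ranks break lexicographically; identical
  inputs give identical outputs, including byte-identical CSV and newick.
* Cosine delta clamps tiny negative round-off to 0 and symmetrizes
  explicitly; all-zero z-rows (a sample with no variance on the retained
  features) raise a classed degenerate-sample error rather than NaN.
* Fewer than 4 tokens cannot be quartered; fewer than 2 samples cannot be
  standardized; zero-variance groups cannot be t-tested — each raises a
  classed error.
* Quarter remainders go to the earliest quarters ("equal-length" is
  under-specified otherwise); the choice is asserted by a bookkeeping test
  (10,007 tokens → 2502/2502/2502/2501).
* Newick labels have `,();:[]` and whitespace replaced by underscores.

## Problem sizes

The test suite and the acceptance script run the synthetic studies at the
reference conditions (28-text design, 20,000 words per pairing, 1,000 MFW),
with 50 seeds for null calibration, 20 for leaf pairing and 10–20 per
mixing-weight level for the monotonicity trend; consensus-network sweeps in
the scripted analyses use 100–2,000 in steps of 100. These sizes were
chosen so the full suite exercises every stage at realistic corpus scale.

## Known limitations

* The caps-lock convention is assumed strict; mixed-case prompts would leak
  facilitator text into the user stream.
* Tokenizer dialect, linkage, and the consensus-network edge rule are
  reconstructions of under-specified conventions; all are exposed as
  configuration, and replication against external corpora should be read
  per configuration.
* The scalar-distance classification feature explains the group
  classification setup only approximately; multivariate representations
  would be non-replicative extensions.
* Real-corpus token totals depend on tokenization details (elision,
  culling) that can shift counts by small margins under any reconstruction.
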