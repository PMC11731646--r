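# costylo

Stylometric co-authorship analysis for facilitated-communication (FC)
dialogue corpora.

In facilitated communication, a user types with physical support from a
facilitator, and the central empirical question is one of authorship: do
the produced texts carry a detectable stylistic signature of the user, or
only of the facilitator? `costylo` treats this as an authorship-attribution
problem and provides the full quantitative pipeline, aimed at
computational-linguistics researchers and anyone auditing attribution
claims on dialogue corpora where the two voices are marked typographically
(facilitator turns in caps lock).

## What it computes

Texts are profiled as most-frequent-feature vectors (top-*k* words or
character trigrams by corpus frequency, relative frequencies per sample),
z-scored per feature across samples, and compared with delta distances:

- cosine delta: `d(a,b) = 1 − (z_a · z_b) / (‖z_a‖ ‖z_b‖)`, in `[0, 2]`;
- Burrows delta: `d(a,b) = mean_f |z_af − z_bf|` (cross-check metric).

On top of the distance tables the package builds:

- **Chunk clustering** — each text is quartered and recombined three ways
  (1+2/3+4, 1+3/2+4, 1+4/2+3); dendrograms are scored for *same-user leaf
  pairing* (a text's first merge partner sharing its user).
- **Red-line rank analysis** — for a text whose facilitator produced *n*
  texts, only the *n − 1* same-facilitator texts should occupy the top
  *n − 1* neighbour ranks if the facilitator is the sole stylistic source;
  same-user texts above that line are breaches. Two permutation nulls are
  provided: uniform ranking, and the facilitator-conditioned null in which
  same-user flags are exchangeable among cross-facilitator neighbours.
- **Five-group pair statistics** — ordered text pairs classified as IU
  (same user), FU (same facilitator + similar users), F, RU, NR; group
  means/SDs, one-sample t-tests, iterated equal-size subsample t-tests,
  and cross-validated classification of pair distances (weighted KNN, SVM).
- **Bootstrap consensus networks** — nearest-neighbour links accumulated
  over a sweep of feature-vector sizes, with per-category link/weight
  summaries and theoretical link maxima.
- **A synthetic corpus generator** — users and facilitators get perturbed
  Zipfian unigram profiles and each token of a pair text is drawn from the
  user's profile with probability λ, else the facilitator's; it also emits
  the caps-lock session-file format, so every pipeline stage (including the
  parser) is testable against ground truth.

## Worked example

The numbered scripts under `analysis/` run the three studies on synthetic
corpora with known structure. `analysis/03_rank_and_groups.R` generates a
28-pairing corpus (10 users × 7 facilitators, 20,000 words per pairing,
mixing weight λ = 0.6) and prints:

```
red line: 47/60 same-user texts breach (uniform null expects 10.2, conditional null 5.6)
same-user placements: 55 top-3, 60 top-5, 60 top-10; first among shared-facilitator group 60/60
group distance summary:
 group   n      mean         sd
    IU  60 0.8455087 0.02829089
    FU  33 0.9807411 0.03404027
     F 109 0.9838483 0.03398879
    RU 117 1.0770288 0.03563273
    NR 437 1.0700993 0.03296012
iterated subsample tests (IU vs each group), mean p over 10 draws:
  IU vs FU  mean p = 0.0000  reject
  IU vs F   mean p = 0.0000  reject
  IU vs RU  mean p = 0.0000  reject
  IU vs NR  mean p = 0.0000  reject
weighted_knn accuracy: 85.1%
svm accuracy: 74.1%
```

Reading this: 47 of the 60 same-user rank observations rise above the
facilitator red line — far beyond either null — because the generator
planted a user signal (λ = 0.6). Same-user texts (IU) are much closer on
average (0.85) than unrelated texts (NR, 1.07), the group counts
(60/33/109/117/437, summing to 28×27 = 756) are fixed by the design and
similarity map alone, and the iterated tests separate IU from every other
group. With λ = 0 the same pipeline reports ~0 breaches, inside the
conditional null's central 95% interval (see
`analysis/05_null_calibration.R`).

Minimal programmatic use:

```r
library(costylo)
corp <- generate_corpus(center2_design(), lambda = 0.6,
                        words_per_pair = 20000, seed = 102)
res <- run_study2(corp$samples, corp$meta, center2_similarity(),
                  mfw = 1000, sweep = seq(100, 2000, 100))
res$report$breaches        # same-user texts above the red line
res$groups                 # IU/FU/F/RU/NR distance statistics
```

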