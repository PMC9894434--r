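---
title: "Measuring verbal veracity cues: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring verbal veracity cues: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veracue)
```

## The problem

Deception research has long asked whether lying leaves measurable traces in
language: lies are hypothesized to be cognitively more demanding to produce,
which should show up as shorter, simpler, less abstract statements, with
characteristic shifts in sentiment and person reference. `veracue`
implements a reproducible pipeline for testing such hypotheses on corpora of
dependency-parsed statements collected in a within-subject 2×2 design: each
subject produces a truthful and a deceptive statement in each of two
modalities (typed text and transcribed speech).

The pipeline is deliberately parser-agnostic. Dependency parsing and
morphological tagging are upstream concerns; `veracue` consumes their output
in standard CoNLL-U form (10 tab-separated columns, 1-based token indices,
`HEAD = 0` marking the root) and validates the tree structure of every
sentence on load. Multiword-token ranges and empty nodes are skipped
throughout: they have no unique surface position, so they cannot enter
distance computations coherently.

## The feature battery

The default battery has 43 variables per statement:

* **Length (3)** — sentence count, token count, and non-whitespace character
  count of the raw text.
* **Syntactic complexity (2)** — mean dependency distance (MDD) and mean
  hierarchical distance (MHD). For a sentence of $n$ tokens with head
  function $h(\cdot)$, MDD is the mean of $|i - h(i)|$ over the $n-1$
  dependency pairs, and MHD is the mean number of edges on the path from
  each non-root token to the root. Both are pure functions of tree
  structure, bounded below by 1, and serve as proxies for the working-memory
  load of producing the sentence.
* **Readability (1)** — the Gunning Fog index,
  $0.4\,(\text{words}/\text{sentences} + 100\,\text{complex}/\text{words})$,
  with complex words defined as three or more syllables.
* **Lexical abstraction (5)** — Linguistic Category Model (LCM) counts of
  descriptive action verbs (DAV), interpretative action verbs (IAV), state
  verbs (SV), and subject-modifying adjectives (ADJ), plus the recommended
  weighted score $\mathrm{DAV} + 2\,\mathrm{IAV} + 3\,\mathrm{SV} +
  4\,\mathrm{ADJ}$; weights increase with abstractness.
* **Sentiment (2), negations (1), over-generalizations (1)** — token counts
  of lemma matches against category lexicons.
* **Detailed part of speech (28)** — counts of NKJP/Morfeusz-style tags
  keyed on the first colon-separated XPOS segment, including the
  theoretically interesting `ppron12` (first/second-person pronouns),
  `ppron3` (third-person pronouns), and `inf` (infinitives).

Raw counts are stored unnormalized in the feature table; normalization is
the statistical stage's responsibility, so the same table feeds both
analyses without ambiguity about what was divided by what.

### Aggregation and edge cases

Statement-level MDD/MHD is the unweighted mean of per-sentence values over
sentences with at least two tokens. This treats sentences as exchangeable
units; an edge-pooled alternative (weighting sentences by their edge count)
is available via `aggregate = "pooled"` in `statement_complexity()`. One-token
sentences contribute no dependency pair and are excluded; a statement with
no eligible sentence gets `NA`, never a silent zero. The same philosophy
holds everywhere: a missing lexicon leaves its columns `NA`, and downstream
stages drop and log incomplete rows rather than imputing.

The Fog index was designed for passages of at least 100 words, but the
statements in this design are scored whole regardless of length (a
configurable warning threshold is available). Punctuation tokens are
excluded from Fog word counts; they are retained in MDD/MHD when the parser
attached them, with a config flag to drop them there too, since parsers
differ in how they treat punctuation attachment.

### Syllable counting

The default counter returns the number of maximal vowel-letter runs, with
the Polish vowel inventory (a, e, i, o, u, y, ó, ą, ę) and prevocalic *i*
merged into the following nucleus (in Polish orthography it usually marks
palatalization, as in *nie* — one syllable). This is a heuristic: it has no
exception dictionary and will miscount loanwords and hiatus. The counter is
therefore pluggable (`syllable_fun` in `feature_config()`); any
`character -> integer` function can replace it, and Fog inherits whatever
convention it encodes.

### Adjective filtering

The LCM counts only adjectives that modify subject nouns. We operationalize
this through the parse: a token qualifies when its relation is in
`amod_deprels` (default `amod`) and its head's relation is in
`subject_deprels` (default `nsubj`). Annotation schemes differ in how they
label passive and clausal subjects, so both lists are configuration, not
code. Predicative adjectives (copular constructions, where the adjective
heads the clause) do not qualify under the default.

## The statistical stage

Each feature is analyzed with the same model. Count-family features are
first divided by the statement's token count; then every variable is
transformed as $y = \log(x + 1)$. Adding 1 before the log keeps zeros at
zero and every transformed value finite; for rates, forming the rate
*before* the +1 keeps the transformed scale comparable across statements of
different lengths. The fitted model is a random-intercept regression

$$y_{ij} = \beta_0 + \beta_v v_{ij} + \beta_m m_{ij} + \beta_{vm} v_{ij} m_{ij}
          + u_i + \varepsilon_{ij},$$

with sum contrasts $v = -0.5$ (truth) $/ +0.5$ (lie) and $m = -0.5$
(written) $/ +0.5$ (transcribed), so each main effect estimates the
condition difference averaged over the other factor, and the subject
intercept $u_i \sim N(0, \sigma_u^2)$ absorbs the repeated-measures
dependence among one person's four statements.

### Fitting

The fit is REML with the variance ratio $\lambda = \sigma_u^2/\sigma^2$
profiled: for fixed $\lambda$, the marginal covariance is block diagonal
with blocks $I + \lambda J$, so $V^{-1}$ and $\log|V|$ have closed forms per
subject (Woodbury identity), GLS gives $\hat\beta(\lambda)$ and
$\hat\sigma^2(\lambda)$ directly, and the REML criterion reduces to a
one-dimensional function of $\lambda$. That function is optimized by
`stats::optimize()` on $[0, 10^4]$ with tolerance $10^{-8}$; because the
bounded search cannot return the boundary exactly, the criterion is also
evaluated at $\lambda = 0$ and the boundary is taken when it is at least as
good. The procedure is deterministic — no random starts — and the test suite
verifies agreement with `lme4::lmer()` to $10^{-6}$ on the fixed effects and
the returned $\lambda$ against a 50-point criterion grid.

Two degenerate cases are handled explicitly: with zero subject variance the
fit collapses to OLS (verified against the closed form), and a constant
response returns the exact zero-variance fit rather than an optimizer
artifact.

### Inference

P-values are Wald normal approximations, $p = 2\Phi(-|b/\mathrm{se}|)$.
Mixed models have no unambiguous residual degrees of freedom; with ~1600
observations and ~400 subjects the normal approximation is accurate, and it
keeps the pipeline deterministic and dependency-free. A Satterthwaite
correction would be the natural extension for small designs.

Multiplicity is controlled with Holm's step-down correction. The family is
the set of analyzed dependent variables *within each effect* (one family for
veracity, one for modality, one for the interaction): the veracity contrast
is the scientific question and the other two are controls, so pooling them
would trade veracity power against control-effect multiplicity. A pooled
mode (`holm_family = "pooled"`) is provided for sensitivity analysis.

Variables with fewer than `min_n` non-missing values or with zero variance
are skipped and reported in the `skipped` attribute — on synthetic corpora
several of the 28 tracked POS tags never occur, and silently fitting a
constant would produce meaningless Wald statistics.

## Classification

The truth/lie classifier consumes the same battery with count features as
per-token rates. Cross-validation is 20-fold and **group-aware by
default**: all four statements of a subject share a fold. With repeated
statements per author, naive folding lets the model memorize author style
and leak it into test folds; group-aware folding is the honest protocol, and
a non-grouped mode exists for comparison with protocols that ignore the
issue. Fold columns are z-scored using training-fold statistics only — the
test suite asserts this structurally. The reported summary is the mean fold
accuracy ± $\mathrm{sd}(\text{folds})/\sqrt{k}$.

The native baseline is an L2-regularized logistic regression fitted by
full-batch gradient descent with a Lipschitz step size — deterministic and
free of external dependencies. SVM-RBF (`e1071`) and gradient boosting
(`xgboost`) adapters plug into the same interface with library-default
hyperparameters; no tuning is performed by design, since accuracy
comparisons across untuned learners are already informative about feature
quality.

## The synthetic-data generator

No public corpus accompanies this design, so the generator is a first-class
module: it emulates the study conditions — 400 subjects × 4 statements in
the 2×2 within-subject layout (1600 statements) — with fully recorded ground
truth.

Every manipulable quantity lives on a latent scale: logit for emission
probabilities and the tree-shape parameter, log for sentence/token counts
and syllables per word. Condition effects are latent-scale coefficients
multiplied by the same ±0.5 contrasts the analysis stage uses, and subject
intercepts are Gaussian on the latent scale (default $\sigma = 0.3$), so the
random-intercept model's estimand equals the planted coefficient and
parameter recovery is a meaningful check rather than a tautology.

Statements are built token by token: each slot draws a cue family
(LCM class, sentiment polarity, negation, over-generalization, pronoun
class, infinitive, or filler) from condition-shifted categorical
probabilities; lemmas come from synthetic lexicons of distinct two-syllable
consonant-vowel strings (so lexicon families are disjoint by construction
and the syllable counter is exercised for real); filler surface forms carry
$1 + \mathrm{Poisson}$ syllables with a condition-shiftable mean, which is
what moves Fog. Trees come from a chain/star mixture: each token attaches to
its predecessor with probability `shape` and to the root otherwise, so
`shape = 0` gives a star (MHD exactly 1), `shape = 1` a chain (MDD exactly 1,
MHD exactly $n/2$), and intermediate values interpolate expected depth —
giving MDD/MHD controllable targets with known limits.

Default scales — 5 sentences and 12 tokens per sentence on average —
reflect short opinion statements of one to two minutes of speech or a few
typed paragraphs.

Three presets fix the study conditions: `null` (no condition effects, for
calibration), `paper_like` (modest latent shifts in the directions the
deception literature reports: truths longer, foggier and more abstract; lies
with more positive and fewer negative sentiment words and more infinitives;
speech longer and syntactically more complex than writing), and `strong`
(large veracity shifts across several families, for classifier checks).

What the generator does **not** emulate: real Polish morphology and syntax,
topicality, discourse structure, parser errors, transcription noise, or
correlations between cue families beyond those induced by shared lengths
and intercepts. Passing tests on synthetic corpora therefore demonstrate
that the pipeline measures what it claims and recovers what was planted —
not that any particular cue separates truth from lies in real speech.

## Verification and problem sizes

The test suite checks, among other things: the six-token worked example
whose MDD and MHD both equal 1.6 exactly; equivalence of MDD/MHD with
brute-force recomputation on 1,000 random trees to $10^{-12}$; chain/star
closed forms for $k = 2..50$; Holm against a brute-force implementation and
`stats::p.adjust` on 1,000 random p-vectors; REML against OLS (zero subject
variance) and `lme4`; 100-replicate recovery of a planted veracity effect
($\beta_v = 0.3$, $\sigma_u = \sigma = 0.5$, 100 subjects) with nominal
Wald coverage; type-I calibration of the raw veracity p-values across the
battery on a 400-subject null corpus; chance-level group-aware CV on the
null corpus and ≥ 0.70 accuracy under the `strong` preset; and byte-identical
reruns of the full simulate → extract → analyze → classify pipeline at a
fixed seed (40 subjects). These sizes were chosen to give tight checks at
interactive runtimes; the generator itself scales linearly and runs the full
400-subject design in seconds.

## Known limitations

* The syllable heuristic has no exception list; Fog values inherit its
  conventions.
* Wald normal p-values are anticonservative for very small subject counts;
  below a few dozen subjects a df correction would be preferable.
* The battery's exact 43-variable composition is a documented default, not
  a canon: the POS tag list is configuration, and analyses should report
  the list they used.
* Sentiment/LCM matching is exact lemma lookup — no sense disambiguation,
  no negation-scope handling (a negated positive word still counts as
  positive).
* The REML implementation covers the single random-intercept design this
  pipeline needs; random slopes or crossed effects are out of scope.
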