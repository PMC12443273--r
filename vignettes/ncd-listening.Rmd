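---
title: "Mining social-media comments about non-communicable diseases with ncdlisten"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining social-media comments about non-communicable diseases with ncdlisten}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdlisten)
```

## What the package does

Public comment threads under health-related posts carry a lot of usable
signal about how people experience non-communicable diseases (NCDs):
which diseases are discussed, what symptoms and treatments come up, whose
experience is being shared, and what people want to know. `ncdlisten`
implements an offline, fully testable back end for listening to such
threads in Thai and English:

1. **Ingestion** — parse saved comment-section HTML (via per-platform CSS
   selector configurations) or four-column CSV exports
   (`name,comments,likes,replies`) into a comment table; deduplicate,
   drop very short comments, anonymize.
2. **NLP core** — language detection, tokenization (dictionary-based
   segmentation for Thai), stopword removal, normalization.
3. **Knowledge extraction** — lexicon matching that fills the per-comment
   dashboard variables, plus the user-driven include/exclude filter.
4. **Classification** — each comment is assigned one of three categories:
   *sharing experience*, *inquiring*, *non-informative*.
5. **Summarization** — retrieval-augmented generation behind a pluggable
   backend contract, with a deterministic offline mock.
6. **Dashboard model** — chart aggregation with user-validated visibility
   defaults, filtering, and exports.
7. **Evaluation statistics** — Likert interpretation bins, Mann-Whitney U
   with mean ranks, and a-priori power analysis for two-sample t tests.
8. **Synthetic data** — seeded generators for every input, with recorded
   ground truth, so all of the above is testable with no network and no
   platform access.

This vignette explains the modeling and numerical choices. Nothing here
states an empirical result that the test suite does not itself compute.

## Cleaning rules

Three rules turn a scraped table into an analyzable one.

**Duplicates.** Two comments are duplicates when their texts are identical
after trimming outer whitespace and collapsing internal whitespace runs,
case-sensitively. Exact matching is deliberately conservative: near-duplicate
detection (edit distance, shingling) would silently merge distinct
short comments, and reproducibility matters more here than recall. The
first occurrence is kept.

**Short comments.** Comments of five or fewer tokens are removed; six or
more are kept. "Token" must be defined per script: Thai is written without
spaces, so Thai comments are counted in dictionary-segmentation tokens,
while English (and unknown-language, with a warning) comments are counted
in whitespace tokens.

**Anonymization.** Every commenter alias is replaced with the literal
token `Name(n)`, where `n` is the comment's sequence number. `seq` is
assigned once, at scrape/read time, and *never renumbered* by later
cleaning stages, so `Name(7)` always refers to the seventh comment of the
original thread — stable references survive re-filtering.

Cleaning order is deduplicate → short filter → anonymize. Duplicates are
removed first so that a duplicated short comment counts once in the
removal log.

Platform like counts rendered as `1.2K`/`3M` are parsed to integers
(rounded thousands/millions).

## Bilingual text handling

**Language detection** looks at the fraction of alphabetic characters in
the Thai Unicode block (U+0E00–U+0E7F); above 0.5 the comment is Thai,
and symmetrically for Latin. Mixed-script comments get the majority
script; text with no letters is `unknown`. The threshold is a config
argument, but 0.5 ("majority script") is the only principled default for
code-switched comments.

**Thai segmentation** is longest-match dictionary segmentation over a
curated dictionary shipped with the package (`inst/extdata/thai_dictionary.txt`,
~170 entries covering NCD vocabulary, pronouns, kin terms, particles and
common verbs). Out-of-dictionary character runs collapse into single
unknown tokens rather than being dropped, so token counts stay meaningful
for the short-comment filter. The dictionary is intentionally small and
user-extensible; a small dictionary under-segments rare words, which is
conservative for the 5-token filter (it can only make comments look
shorter than they are in the unknown-run case, never longer).

**English normalization** is a rule-plus-exception lemmatizer: a shipped
exception table for irregular forms, then light suffix stripping
(plural `-s/-es/-ies`, past `-ed/-ied`, progressive `-ing` with
doubled-consonant repair). It is deliberately not a full morphological
analyzer; what matters is that lexicon terms and comment tokens are
normalized by the *same* function, so matching is consistent even where
the stem is imperfect. Thai has no inflectional morphology to lemmatize;
Thai normalization is orthographic only (Unicode NFC plus collapsing
accidentally doubled tone/vowel marks).

**Emoji and URLs** are stripped before tokenization: both pollute keyword
matching and word-frequency charts.

Stopword lists ship as plain-text resources (one token per line) and can
be overridden per call.

## Lexicon matching

The lexicon is YAML: category → entries `{label, en: [...], th: [...]}`
over six categories (`disease`, `symptom`, `treatment`, `behavior_cause`,
`gender_cue`, `source_cue`). The starter lexicon covers the four classic
NCD groups (cancer, cardiovascular disease, diabetes, chronic respiratory
disease) plus hypertension; it is a starting point, not a validated
clinical vocabulary, and real deployments should extend it.

Matching is asymmetric by script, on purpose:

- **English terms** are matched as contiguous subsequences of the
  normalized token stream. Content categories match after stopword
  removal (so "shortness of breath" matches "shortness ... breath"); the
  two *cue* categories match on the full normalized token stream, because
  pronouns and particles — exactly the tokens a stoplist removes — *are*
  the cues.
- **Thai terms** are matched as substrings of the raw, unsegmented text,
  because dictionary segmentation can split a lexicon term the dictionary
  does not contain. Thai lexicon entries should therefore be at least two
  characters and unambiguous as substrings.

Per-comment variables: mentioned diseases/symptoms/treatments/behaviors
are the matched label sets (deduplicated, first-occurrence order; each
comment counts once per label downstream). **Gender** comes only from
explicit cue words (pronouns, polite particles, kin self-descriptors);
cues for both genders in one comment yield `unknown`. No name-based
gender guessing is done — names are anonymized away precisely to avoid
re-identification. **Opinion source** uses the taxonomy
`self / family_member / acquaintance / general / unknown`, first matched
cue wins, `general` when no cue is present.

The include/exclude adjustment keeps a comment iff (the include set is
empty or the comment mentions an included disease/symptom) and it mentions
no excluded label — monotone, idempotent, always a subset of its input.

## Classification

The three-category taxonomy is fixed. Three backends implement the
`classify(text) → label` contract:

- `rule_based` (default, no training): interrogative cues (question marks,
  sentence-initial wh-/auxiliary words, Thai question particles such as
  ไหม/หรือเปล่า/ทำไม) → *inquiring*; otherwise first-person experience cues
  (I/my/me, ผมเป็น/ฉันเคย/…) → *sharing experience*; otherwise
  *non-informative*. Total and deterministic.
- `linear_bow`: bag-of-words over normalized tokens, multinomial ridge
  regression (glmnet, fixed small penalty, no internal cross-validation so
  a seed fully determines the fit). This is the desk-scale trainable
  model used in tests.
- `transformer`: the fine-tuning recipe is plumbing-only. The
  configuration carries the recipe's knobs — 70/30 stratified split,
  minority-class oversampling by seeded duplication, maximum sequence
  length 200, learning rate 2e-5, early stopping on a stratified 10%
  validation carve-out with patience 3 — but the actual fit is delegated
  to a user-supplied function, and nothing is ever downloaded. The
  sequence-length limit is expressed in tokenizer units; patience 3 and
  the 10% validation fraction are package defaults for knobs whose values
  the recipe leaves open.

Oversampling duplicates minority-class items (seeded) until all classes
match the majority count; it is applied to the training partition only,
and a dedicated test asserts no duplicated item ever appears in the test
partition. Evaluation builds the 3×3 confusion matrix (rows = gold) and
one-vs-rest precision/recall/F1 plus trace-accuracy.

## Retrieval-augmented summarization

Comments are embedded, indexed, and the `k` most similar comments to the
chosen approach's question are placed into a fixed prompt template for a
text-generation backend.

- The two question texts (a *general* characterization question and a
  *medical-focus* disease/symptom question) are fixed verbatim, and a
  golden-string test guards every byte. The framing instructs the
  generator to answer in English using only the supplied context.
- The default embedder is seeded feature hashing of normalized tokens into
  a 256-dimensional L2-normalized vector (a pure-R polynomial rolling hash;
  two independent hash streams give bucket and sign). It is deterministic
  across platforms and knows nothing about semantics — it is the offline
  stand-in behind the same contract a remote embedding service would
  implement.
- Retrieval ranks by cosine similarity, descending, ties broken by lower
  comment `seq`; `k` defaults to 20 and is configurable, since no single
  retrieval depth is canonical.
- The test/mock generation backend emits a deterministic digest (context
  size plus sorted matched disease labels) so pipeline behavior is
  assertable offline; an empty retrieved set renders an explicit
  `[no context retrieved]` marker rather than silently truncating.

No network access occurs anywhere in the package or its tests.

## Dashboard model

Eight variables are aggregated per post: patient gender (pie), opinion
source (pie), categorized comments (pie), mentioned
diseases/symptoms/treatments/behaviors (bars), and top-20 word frequency
(bar). Default visibility follows the user-assessment rule that only
variables whose mean importance rating reached at least 4.21 on the
5-point scale are shown: gender, diseases, symptoms, treatments and
behaviors are visible; source, categorized comments and word frequency
are hidden but always retrievable. Comments with unknown gender are
excluded from the gender pie (they would dominate it) but remain in the
summary table. Bars count each comment once per mentioned label; counts
are ordered descending with lexicographic ties. Refiltering delegates to
the include/exclude rule, re-aggregates every chart, and marks any
existing summary stale until regenerated. Reports are structured JSON
(every chart's data, active filters, summary text); PDF rendering is a
presentation concern left out deliberately.

## Evaluation statistics

**Power analysis.** For a two-independent-sample t test with effect size
`d`, the noncentrality parameter is `δ = d·√(n1·n2/(n1+n2))`, the
rejection threshold is the upper central-t quantile at `α` (one-tailed)
or `α/2` (two-tailed) with `df = n1+n2−2`, and achieved power is the
noncentral-t tail mass beyond it (plus the opposite tail for two-tailed
tests). `required_sample_size()` scans n1 upward (n2 = ceiling of the
allocation ratio times n1) until the target power is met, and reports the
full quantity set: n1, n2, df, δ, critical t, achieved power. The
noncentral-t CDF is R's `pt(..., ncp = )`; tests cross-check against
`power.t.test` and a Monte-Carlo simulation. With `d = 0.80`, `α = 0.10`,
one tail and target power 0.80 this yields 15 participants per group
(df 28, δ 2.19, critical t 1.31, achieved power 0.81) — the design used
to size a 30-participant evaluation study, reproduced analytically by
`scripts/acceptance.R`.

**Mann-Whitney U.** Pooled midranks; `U = R1 − n1(n1+1)/2`; per-group mean
ranks reported alongside, as survey software tabulates them. For small
problems (`n1·n2 ≤ 64`) the p value is exact, from the permutation null
distribution of U over all group assignments (midranks preserved, so ties
are handled exactly). Larger problems use the normal approximation with
tie-corrected variance and *no* continuity correction — the convention of
the mainstream survey-statistics packages this module mirrors. The
two-sided exact p is the symmetric-distance definition
`P(|U − n1n2/2| ≥ |u − n1n2/2|)`, which coincides with the doubled-tail
definition because the null distribution of U is symmetric. All values
identical across both groups is flagged and returns p = 1.

**Likert bins.** Mean scores are rounded half-up at 2 decimals (base R's
`round()` is half-even, so the package uses an explicit half-up rule with
a 1e-9 guard against binary representation error) and mapped to
1.00–1.80 Very Poor, 1.81–2.60 Poor, 2.61–3.40 Moderate, 3.41–4.20 Good,
4.21–5.00 Very Good. The bins tile the 2-decimal grid exactly; an
exhaustive 0.01-step sweep in the tests verifies it.

## Synthetic data: what it emulates and what it does not

`generate_corpus()` builds bilingual corpora from class-specific
templates: inquiring templates carry interrogative cues, sharing
templates carry first-person or kin perspective cues plus planted lexicon
terms, non-informative templates carry neither. Exact duplicates and
≤5-token comments are injected at configurable rates, and the returned
ground truth records every planted label, mention, expected gender/source,
duplicate link and short flag — each pipeline stage is checkable against
it without hand-labeling.

Defaults (chosen once as a plausible NCD comment thread, and not tuned):
100 comments, 50/50 Thai/English, class mixture 0.55 sharing / 0.15
inquiring / 0.30 non-informative (inquiring is the minority, as it is in
real health threads), mention rates 0.8 disease / 0.5 symptom / 0.4
treatment / 0.3 behavior among substantive comments, 5% duplicates, 10%
short comments. The Thai side uses a small curated sentence bank with
term slots, since no Thai corpus ships with the package.

What the generator does **not** emulate: real lexical diversity, slang,
typos, sarcasm, negation ("never smoked"), code-switching within a
sentence, or annotation ambiguity between *inquiring* and narrative text.
Consequently, passing tests demonstrate that the machinery is correct —
filters remove exactly what they should, matching agrees with brute-force
scans, the trainable classifier recovers planted separable vocabularies —
not that any fixed accuracy will hold on real platform data. In
particular the ≥90% held-out recovery of `linear_bow` on generated
corpora is a property of separable templates, not a field performance
claim.

`generate_fixture_html()` renders comment tables into HTML matching a
selector configuration (simple `tag.class` selectors), so the parser is
exercised on round-trips, including markup-hostile characters.
`generate_likert_responses()` discretizes a logistic latent scale onto
1–5; group 2's latent location is shifted down by `shift`, giving
stochastic dominance, and `shift = 0` makes the groups exchangeable —
which is what the type-I-error test of the Mann-Whitney module relies on.

## Numerical and scale choices in the test suite

Tests size their simulations to run comfortably on one CPU: 1,000-comment
corpora for the brute-force matching and retrieval-equivalence checks,
300 comments for classifier recovery, exhaustive permutation up to group
sizes 6×6, a 1,000-replicate type-I-error simulation at 15 per group (the
evaluated study's own group size), and 4,000-replicate Monte-Carlo
cross-checks of power. Every stochastic step is seeded; the suite is
deterministic end to end.

## Known limitations

- Lexicon matching has no negation or uncertainty handling; "never had
  cancer" counts as a cancer mention. Semantic matching is an explicit
  non-goal here.
- The starter lexicon and Thai dictionary are small curated artifacts;
  coverage on real threads requires extension.
- Gender and source are cue-based readings of the *commenter's phrasing*,
  not verified patient attributes.
- The transformer backend is a contract, not a model: desk-scale
  environments get the rule-based and linear models only.
- Exact Mann-Whitney enumeration is limited to `n1·n2 ≤ 64`; beyond that
  the tie-corrected normal approximation is used.
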