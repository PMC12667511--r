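---
title: "Hierarchical record linkage: method, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical record linkage: method, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierlink)
library(data.table)
```

## The problem

Brazilian public-health registries such as the mortality information system
(SIM) and the severe acute respiratory illness surveillance system
(SIVEP-Gripe) record overlapping populations but share no unique person
identifier. Establishing which rows refer to the same individual must
therefore rely on quasi-identifiers — full name, mother's name, and date of
birth — all of which are typed by hand and carry misspellings, missing
fields, swapped date components, and name-order variation.

`hierlink` implements a hierarchical hybrid strategy for this setting. The
guiding idea is *stepwise refinement*: the most stringent criteria run
first, each accepted link retires both records, and progressively looser
criteria only ever see what earlier steps could not resolve. This gives
every record at most one final match status while letting late steps
tolerate substantial typographical damage without flooding the result with
false positives.

## The matching model

### Deterministic steps: statistical linkage keys

Steps 1–2 require exact equality of a *statistical linkage key* (SLK), a
pseudo-identifier concatenating the canonical name, mother's name and date
of birth. Step 1 uses the full mother's name; step 2 drops the mother's
final surname, absorbing the common inconsistency where one registry
records a married surname the other lacks. A key is undefined (and the
record skips the step) whenever any component is missing: a partial key
would collide across unrelated people. Components are joined with `"|"` so
that token boundaries remain unambiguous (`"ANA B" + "C"` cannot collide
with `"ANA" + "B C"`).

### Probabilistic steps: blocked similarity comparison

Steps 3–13 accept a pair when a weighted mean of string similarities
strictly exceeds a per-step threshold:

$$ S(l, r) \;=\; \frac{\sum_i w_i \, \mathrm{sim}\big(l_{f_i},\, r_{f_i}\big)}{\sum_i w_i} \;>\; \tau $$

where `sim` is Jaro or Jaro–Winkler and the fields $f_i$ range over the
joined name, the mother's name, their trimmed variants, individual name
tokens, and the date rendered as the digit string `YYYYMMDD`. Comparing the
date as a *string* inside the average lets a single mistyped digit degrade
the score gracefully instead of vetoing the pair; zero padding keeps digit
positions aligned. A weight of 2 on the name means weight, not string
duplication — the divisor is the sum of weights, keeping scores in [0, 1].
A component missing on either side contributes zero while keeping its
weight in the divisor, so incompleteness is penalized, never ignored.

Each probabilistic step restricts comparison to *blocked* candidate pairs:
pairs agreeing exactly on that step's blocking keys (first name, second
name, the mother's-name analogues, and date parts, in step-specific
combinations). Blocking is what makes the quadratic comparison tractable,
and the 13 steps vary their blocking keys so that an error in any one field
still leaves several steps whose keys avoid it.

### String similarity

The Jaro similarity of strings $a, b$ counts characters matching within a
sliding window of $\lfloor \max(|a|,|b|)/2 \rfloor - 1$ positions and the
number $t$ of transposed matched pairs:

$$ J = \frac{1}{3}\left(\frac{m}{|a|} + \frac{m}{|b|} + \frac{m - t}{m}\right) $$

Jaro–Winkler adds $\ell \, p \, (1 - J)$ when $J$ exceeds a boost
threshold, with $\ell$ the shared prefix length capped at `max_prefix` —
rewarding prefixes suits person names, whose first characters are typed
most reliably. The constants default to the canonical Winkler values
$p = 0.1$, `max_prefix` = 4, boost threshold 0.7, the same semantics as the
widespread SQL and Python implementations; all three are settable through
`similarity_params()`. Conventions: two empty strings score 1 (identity
holds universally); empty versus non-empty scores 0. The kernel is written
in C++ for speed and is cross-checked in the test suite against an
independent pure-R implementation written directly from the definition.

### One-to-one resolution

Surveillance practice reports one match status per record, so each step's
supra-threshold pairs are resolved to a one-to-one matching: greedy
selection by descending score, ties broken lexicographically by
`(left_id, right_id)`. Greedy resolution with a deterministic tie-break
makes every run exactly reproducible; a maximum-weight matching could
differ on contrived score patterns but would sacrifice the simple guarantee
that the best-scoring pair is always kept.

## Normalization choices

Text is uppercased, diacritic-folded to ASCII, stripped of punctuation and
digits, and whitespace-collapsed (`normalize_text()`, idempotent).
Tokenization removes the Portuguese connective particles DA, DE, DO, DAS,
DOS, E before assigning first/second/last roles — "second name" means the
second remaining token, and with exactly two tokens the second and last
name coincide. Whether particles should also be removed from blocking keys
is genuinely open; removing them makes blocking robust to their inconsistent
recording, and the particle list is an argument everywhere it matters, so
either convention is available.

## Evaluation harness

Ground truth attaches to the left registry as `truth_ref`, the id of the
true counterpart (or absent). Per left record: a link to exactly that
counterpart is a true positive; an unlinked positive a false negative; a
linked negative a false positive; an unlinked negative a true negative. A
positive linked to the *wrong* right record counts as both a false positive
and a false negative — conservative double counting that keeps
`TP + FN = positives` while still charging the spurious pair.

`accuracy_report()` derives sensitivity, specificity, PPV, NPV and overall
accuracy, each with a binomial confidence interval over its own
denominator. The Wald interval is the default — it reproduces the interval
arithmetic of the validation tables this harness mirrors — with Wilson and
Clopper–Pearson selectable since published diagnostic tables rarely name
their method. Zero-denominator metrics are reported as undefined, never
as 0. Display rounding is half-up to three decimals.

## The synthetic benchmark

Real SIM / SIVEP-Gripe extracts contain personally identifying information
and are access-restricted, so the package validates the engine on generated
registries with known ground truth, reproducing the injection design of the
study it follows: a fixed set of true positives is corrupted and planted in
a right-side registry among independent distractors, while the left
registry holds the positive originals plus a negative pool sized to hit a
target prevalence (5, 25, 50% by default; the scaled default design uses
1,150 positives against pools of 21,850 / 3,450 / 1,150 — one tenth of the
full published design, which `scale = 1` restores).

```{r benchmark}
bench <- build_benchmark(cohort_design(200, 800, seed = 42), corruption_config())
res <- link_registries(bench$test1, bench$test2)
res
accuracy_report(confusion_from_links(res, bench$test1))
```

The generator emulates Brazilian naming: 1–2 given names plus 1–3 surnames
drawn from bundled frequency-ranked name pools, particles inserted with
probability 0.25, the mother sharing a surname with probability 0.6, birth
dates uniform over 1930–2005 (the age span of hospitalized SARI cases).
The corruption model applies eight operators independently per record —
character substitution (rate 0.05), adjacent transposition (0.02), deletion
(0.02), token swap (0.02), final-surname drop (0.05), mother's-name
blanking (0.03), day/month swap (0.02), single-digit date error (0.02) —
character-level operators hitting the name and the mother's name
independently. Rates are per-operator probabilities, settable individually,
with a global `scale` multiplier for stress sweeps.

What the generator does *not* emulate: the true name/date frequency
distributions of the registries, household structure, homonym clusters, or
correlated field-missingness. Passing benchmarks therefore demonstrate the
engine's mechanics (completeness on clean duplicates, graceful degradation
under typographical noise, zero accidental links among independent people)
— not the exact accuracy figures to expect on restricted production data.

## Numerical and degenerate-input choices

* Thresholds are strict (`>`), exactly as specified per step.
* Dates failing calendar validation are rejected at read time with the
  offending row; date corruption operators only ever emit valid dates.
* A single-token name keeps its token under `drop_last_surname()` (there is
  no surname to drop); an all-particle name tokenizes to nothing and is
  simply ineligible for steps needing name fields.
* Records missing a blocking key or an SLK component skip that step but
  remain available to later steps.
* All randomness flows through R's RNG seeded once per benchmark, making
  registries, links and reports byte-for-byte reproducible.

## Validation workloads in the test suite

The shipped tests exercise, among others: the C++ similarity kernel against
a definitional pure-R oracle on 10,000 random string pairs; `run_step()`
against a cross-product brute-force reference on fifty 100×100 registry
pairs across all 13 steps; clean-duplicate completeness (sensitivity 1.0,
zero false positives, all links at step 1) at the scaled three-prevalence
design; and mean-sensitivity monotonicity over 20 seeded replicates of a
(100 positives, 200 negatives) design as corruption rates scale through
{0, 0.5, 1, 2}. These sizes are chosen to keep the whole suite at desk
runtimes while leaving the quadratic oracle comparisons meaningful.

## Known limitations

* Greedy one-to-one resolution is order-robust but not globally optimal.
* The engine targets registries that fit in memory; blocking uses hashed
  equality joins, not disk-backed or sorted-neighborhood indexing.
* No phonetic encoding and no metrics beyond Jaro / Jaro–Winkler; nickname
  and abbreviation expansion are out of scope.
* Accuracy estimates from the synthetic benchmark transfer to real
  registries only to the extent the corruption model matches real error
  processes, which is unknowable without restricted data.
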