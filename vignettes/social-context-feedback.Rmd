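---
title: "Methods: social-context feedback from personal networks and experience sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social-context feedback from personal networks and experience sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egolens)
```

## The assessment design this package models

`egolens` operates on three linked data streams collected from one
participant (the *ego*):

1. **Personal-network waves.** Before and after a diary period, the
   participant names their social contacts (*alters*), rates each
   (role, gender, age bracket, closeness, contact frequency, four
   dichotomous support/disclosure items) and reports which alters have
   contact with each other (undirected ties). At the second elicitation
   all previous ratings and every interaction partner encountered during
   the diary are pre-loaded, so the participant removes, adds and
   re-rates rather than starting over.
2. **Signal-contingent prompts.** For a study period (default 28 days),
   two semi-fixed questionnaires (morning, evening) and a number of
   semi-random prompts (default 4) per day assess momentary affect,
   activities, and whether the participant is alone.
3. **Event-contingent interaction logs.** The participant logs every
   face-to-face, video or phone interaction lasting longer than 5 minutes:
   mode, time, duration, location, type, a free-text description, quality
   indicator ratings (0–10), momentary affect, and the specific partner(s)
   involved. Unknown partners are added to the roster once and reused
   (`register_partner()`; matching is case-insensitive and
   whitespace-collapsed, never fuzzy — a silent merge of two people is a
   worse failure than a duplicate a user can merge by hand).

The feedback report summarises these streams around twelve clinical
questions (`clinical_questions()`), grouped into a network tab and a daily
interactions tab.

## Statistical content

The feedback is deliberately **descriptive**: no regression or multilevel
model is fitted, because the report's role is to support a conversation,
not to test hypotheses.

**Quality summaries.** For a role or partner group with scores
$x_1,\dots,x_n$, the report shows all raw points, the mean $\bar x$, and a
two-sided 95% confidence interval
$\bar x \pm t_{0.975,\,n-1}\, s/\sqrt{n}$. The t-interval is the default
because group sizes are often small (single digits per partner); a
normal-approximation interval is available via `ci_method = "normal"`.
With $n < 2$ no interval is shown rather than a degenerate one. Worked
check: scores $\{6,7,8,9,10\}$ give $\bar x = 8$, $s = 1.5811$,
$t_{0.975,4} = 2.7764$, interval $8 \pm 1.9632$.

**Counting conventions.** A group interaction increments the count of
*every* listed partner, and of each distinct partner role once per event.
Per-partner counts therefore sum to more than the number of events
whenever group events exist; this is intentional (the per-partner panel
answers "how often was this person involved?") and is the only source of
that excess, which is asserted by test.

**Membership reconciliation.** Identity across waves is by stable
`alter_id`, guaranteed by the seeding flow (`seed_post_wave()`), never by
name — a rename is a rating change, not turnover. Statuses partition the
union of pre-wave, post-wave and diary-roster ids. An alter encountered
during the diary but absent from the post wave is classed `removed` with a
warning; this edge case has no canonical treatment, and we read it as the
participant declining to keep the person.

**Perception vs. behaviour.** The discrepancy flag defaults to *closeness
in the top tercile of the wave's ratings and zero logged interactions*.
The clinical question is qualitative; the tercile rule is this package's
operationalisation and the quantile is a parameter
(`closeness_quantile`). All inputs are echoed so users can apply their own
judgement.

**Word frequencies.** Tokens are unicode word sequences, lowercased, no
stemming. Two exclusion lists are applied: ordinary stop words and verbs
that merely restate that a conversation took place (`talking_verbs()`),
since these otherwise dominate interaction descriptions. English and Dutch
lists ship with the package.

## Scales and schedules

Closeness and all quality/affect indicators use a 0–10 scale, contact
frequency a 7-point 0–6 ordinal; all ranges live in one registry
(`scale_registry()`) so they are changeable in one place. Affect and
quality item batteries are open maps (`affect_*`, `quality_*` columns),
not a fixed battery, because instruments vary across studies.

"Semi-random" prompt schedules are generated by **block randomisation**:
the daily random window is split into `n_random` equal blocks, one uniform
draw per block, then a minimum gap (default 30 min) is enforced between
all consecutive same-day prompts by rejection resampling within the block
(100 tries, preserving the uniform-within-block marginal approximately)
followed by a deterministic push-apart fallback. The morning/evening
windows (defaults 08:00–10:00 and 20:00–22:00) are configuration, not
claims about any particular study. Infeasible configurations
(`n_random × min_gap` exceeding the window) are refused at construction.
Compliance is computed per study week (days 1–7, 8–14, …), with
non-compliance stored as a response row with missing `response_time` so
the denominator stays explicit. Participant-initiated interaction logs are
excluded from the compliance denominator and counted separately.

## The on-disk bundle

A dataset is a directory: `manifest.json` (participant id, integer schema
version, file list), `network_waves.json` (nested alters + edge-list ties;
edge lists are sparser and diff-friendlier than adjacency matrices), and
four long-format UTF-8 CSVs (`schedule`, `responses`, `events`, `roster`)
with ISO-8601 timestamps carrying explicit offsets. Output is
deterministic (fixed key and column order), so `write → read → write` is
byte-identical, and unknown schema versions are refused rather than
guessed. Multi-valued cells (partner ids, activities) are
semicolon-joined.

Anonymisation replaces display names with seed-stable pseudonyms
("Contact k" in a seed-determined random order), optionally redacts
free-text descriptions, and optionally shifts all timestamps by one
uniform offset. Ids, ratings, ties and (by default) timestamps are
untouched, so every metric output is invariant under the default
anonymisation — asserted bit-for-bit in the tests.

## What the simulator emulates — and what it does not

`simulate_participant()` generates data with the structure the feedback is
designed to reveal:

* **Networks**: default 42 alters (a realistic median for student
  populations; plausible range 10–80), role-clustered ties with per-role
  within-density (family 0.8 by default — family tends to form a clique)
  and low between-role density (0.04).
* **Interactions**: a Poisson number of events per day (default mean 4);
  partner selection is a categorical draw with weight
  $\propto \exp(\text{closeness}/\tau)$ (default $\tau = 2$), which
  produces the heavy-tailed per-partner count profile seen in real
  diaries. Group events (probability 0.15) draw 2–4 co-partners from the
  primary partner's tie-graph component: people who know each other
  co-occur.
* **Quality**: each alter has a latent mean $\mu_i$ (drawn uniformly in
  [3, 8] unless supplied); event scores are
  $\mathrm{round}(\mathrm{clamp}(N(\mu_i, \sigma), 0, 10))$ with
  $\sigma = 1.5$, matching the integer granularity of 0–10 rating
  sliders. $\mu_i$ is kept away from the scale ends by default so the
  clamp-and-round bias stays far below one scale point.
* **Affect**: the lead affect item follows
  $A_t = b + \varphi\,(A_{t-1} - b) + \gamma\,\bar Q_t + \varepsilon_t$,
  where $\bar Q_t$ is the mean quality of interactions since the previous
  prompt (0 if none), with defaults $b = 6$, $\varphi = 0.4$,
  $\gamma = 0.3$, $\varepsilon_t \sim N(0, 1.5^2)$, clamped and rounded to
  the 0–10 scale. With $\gamma = 0$ the affect–quality correlation is
  indistinguishable from zero; with $\gamma > 0$ affect after high-quality
  interactions exceeds affect after none — exactly the pattern the
  timeline panel is meant to surface.
* **Scenarios**: `breakup` (the romantic partner is re-rated as a friend
  at the post assessment), `growth = k` (k new members first met as diary
  partners), `removals = m`.
* **Content text**: drawn from a small weighted topic vocabulary in which
  food, plans and going(-somewhere) dominate, so the word-cloud pipeline
  has realistic input.

Everything is deterministic given the seed, and every simulated dataset
passes validation and round-trips through the bundle format.

The simulator does **not** emulate: demographic realism beyond role and
age brackets, time-of-day or weekday interaction rhythms, reciprocal
effects of affect on interaction seeking, attrition trends in compliance,
or free text beyond the topic vocabulary. Passing tests therefore show
that the pipeline computes the right statistics on data with the assumed
structure — not that real participants behave like the generator.

## Calibration checks and problem sizes

The test suite and `scripts/acceptance.R` verify, at these scales chosen
to balance statistical resolution against a short default run:

* reconciliation against an independent set-algebra oracle, exhaustively
  over all per-alter membership patterns for up to 4 alters (2,800
  fixtures — every combination of pattern interactions) and 200 random
  fixtures up to 80 alters;
* CI coverage of latent quality means pooled over 24 simulated
  participants × 20 alters (≥ 400 alters with ≥ 30 events each),
  expected ≈ 95% within ±4 percentage points;
* schedule constraints (counts, window containment, minimum gap) by brute
  force over 1,000 generated days;
* zero-noise recovery ($\sigma_i = 0$, integer $\mu_i$): estimated
  per-partner means equal the latent means exactly;
* null coupling ($\gamma = 0$): |r| between affect and same-window quality
  below 0.1 at ≥ 2,000 prompts;
* round-trip identity over 50 simulated seeds and bitwise metric
  invariance under anonymisation.

## Design choices where the design was genuinely open

* **CI method**: t vs normal is not determined by the feedback design;
  t is the default for small-n groups, normal available by config.
* **Event-level vs prompt-level affect in the timeline**: both are
  included, each point tagged with its source, so a report consumer can
  separate them.
* **Ties per wave**: alter–alter ties are stored per wave; cross-wave tie
  change is computed but should be read as exploratory, since re-elicited
  tie rosters are noisy.
* **Rendering**: the report is one self-contained HTML document with the
  payload embedded as JSON and a small hand-written script; no server, no
  external assets. This keeps renders byte-deterministic and every
  displayed number traceable to a payload field — the template computes
  nothing.
* **Sociogram layout**: a force-directed layout with a fixed seed on the
  union graph of both waves, so pre/post panels are directly comparable.

## Known limitations

* Single-ego data only; no sociocentric networks, weighted or directed
  ties.
* Name-based partner registration cannot distinguish two people who share
  a normalised name; they must be split manually.
* The discrepancy rule is a heuristic; with few rated alters the tercile
  threshold is coarse.
* Rating scales are fixed at dataset construction; the registry changes
  ranges globally, not per item.
* The HTML report requires a modern browser with JavaScript; there is no
  static-image fallback.
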