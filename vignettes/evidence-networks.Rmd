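---
title: "Temporal evidence networks: model, dynamics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal evidence networks: model, dynamics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evinet)
library(dplyr)
```

## The problem

Many treatment regimens for the same condition are never compared head to
head in a randomized controlled trial (RCT), and the outcomes that *are*
reported range from response rates through progression-free survival (PFS)
to overall survival. Conventional pairwise meta-analysis cannot aggregate
such a landscape. evinet implements a network meta-analytic approach: each
substantively identical regimen is a vertex, each randomized head-to-head
comparison is an edge (repeat comparisons of the same pair are *parallel*
edges, never collapsed), and every vertex is scored by a simple win/lose/tie
contest scheme. Developing the network year by year exposes how the evidence
base — and the apparent hierarchy of treatments — changed over time.

The pilot context is first-line treatment of chronic-phase chronic
myelogenous leukemia (CML), whose history runs from busulfan and radiation
through hydroxyurea, interferon-α, and imatinib to the second-generation
tyrosine kinase inhibitors. Drug names are data here, not code: the same
machinery applies to any registry in the same tabular schema.

## The registry schema

The input is one row per (trial, unordered comparison):

| column | meaning |
|---|---|
| `trial_id`, `year` | trial identity and publication year (annual resolution) |
| `regimen_a`, `n_a`, `regimen_b`, `n_b` | the two arms and their enrollments (`NA` = not reported) |
| `outcome_class` | `weak` (e.g. response rate), `strong` (e.g. PFS), `os` (overall survival) |
| `verdict` | `a`, `b` (that arm superior) or `tie` |
| `basis` | `sig` (p ≤ 0.05), `noninf` (formal non-inferiority), `ns` (non-significant) |

A decisive verdict requires a significant basis; a tie requires
non-inferiority or non-significance. A k-arm trial must be expanded to all
k(k−1)/2 unordered pairs: this is the only expansion under which the bundled
registry reproduces a multigraph degree of 13 for both imatinib and busulfan,
so it is enforced as a validation invariant rather than left to the data
curator. Regimen labels are canonicalized by splitting on `/`, mapping each
component through an explicit synonym table (which defaults to mapping
nothing — "substantively identical" is a curation judgment and belongs in
data), sorting components case-folded, and re-joining; `IFNA/Imatinib` and
`Imatinib/IFNA` therefore name one vertex. One consequence worth knowing:
labels are re-ordered, so the printed label `IFNA/HiDAC` surfaces as the
canonical `HiDAC/IFNA`.

## Contest valuation

Each comparison is a *contest* seen from each of its two arms: outcome
$E \in \{-1, 0, +1\}$ (lose, tie, win), weighted by the quality of the
measured endpoint, $RV$ = 1.0 for a weak surrogate, 1.25 for a strong
surrogate, 1.5 for overall survival. A vertex with $m$ contests and $N$
patients across those contests (both arms of each contest, each contest
counted once) is valued

$$\hat v \;=\; \frac{1}{m}\sum_{y=1}^{m} RV_y \, E_y \;\times\; \log N .$$

Positive values classify the regimen *superior*, negative *inferior*, and
values inside an `epsilon` band around zero (default 0: a pure sign rule)
*equivocal*. Two numerical guards: $\hat v = 0$ when $m = 0$ or $N \le 1$,
where the logarithm is undefined or zero — a regimen with no interpretable
evidence is equivocal by fiat. Two readings of "patients in all contests
involving the vertex" are possible (both arms of each contest, or only the
regimen's own arms); the contest-sum reading is adopted because the weight
is meant to capture how much randomized evidence the value rests on, and a
contest's information content scales with both arms. The log base defaults
to 10 and is configurable; changing it rescales every value uniformly and
can never change a sign, an ordering, or a classification.

```{r}
vertex_value(tibble::tibble(E = c(1, 0), rv = c(1.5, 1.25),
                            n_compared = c(600, 400)))
```

Antisymmetry ($E_a = -E_b$ unless tie) makes a single comparison zero-sum,
and the valuation is linear in the $RV$ weights; both are enforced as
property tests.

## Visual encoding

* **Node color** — diverging red → yellow → green over the symmetric domain
  $[-\max|\hat v|, +\max|\hat v|]$ of the current snapshot (1 if all values
  are zero), anchors red (255,0,0), yellow (255,255,0), green (0,160,0).
  The anchors and normalization are display choices, not inferences.
* **Node area** — proportional to the cumulative number of patients who
  ever received the regimen (unknown enrollments contribute 0), clamped to
  `[40, 4000]` display units² at 2 units²/patient. Area, not radius: the
  eye reads area.
* **Edge color** — the same three anchors, discrete, by outcome class.
* **Edge width** — linear in the patients compared by the edge's *own*
  trial (clamped `[0.5, 8]` at 0.005/patient); parallel edges are sized
  independently.
* **Alpha opacity** — the recency channel, next.

All constants sit in `valuation_params()` and the YAML config's
`valuation:` section.

## Recency dynamics

Every node and edge starts at alpha 1.0 and decays 0.1 per year to a floor
of 0.2 — a never-refreshed element reaches the floor after 8 years, roughly
matching published estimates of guideline half-life. Nodes are refreshed to
1.0 whenever a new RCT touches them; edges never refresh (their alpha is
their own trial's age). When new evidence flips a node between superior and
inferior, every adjacent node is refreshed to 1.0 — a "look again" signal
that propagates one step, applied once per year (iterating it could change
no value, only alphas). Transitions into or out of equivocal are not flips.

The within-year order of operations is fixed: decay → insert new elements →
refresh touched nodes → revalue everything → cascade on flips → recompute
display attributes. New evidence must be valued before flips can be
detected, and refreshing after decay guarantees that a node touched this
year displays alpha exactly 1.0.

One numerical choice: alphas live on a 0.1 grid, and each decrement is
snapped to 10 decimal places so that repeated subtraction of 0.1 cannot
drift off the grid in floating point. This makes the closed form
`alpha_after(k) = max(0.2, 1 − 0.1k)` agree *exactly* with iterated
`decay_alpha()`, and makes SVG opacity attributes equal model alphas
exactly — both are asserted in the tests.

```{r}
registry <- load_cml_fixture()
timeline <- build_timeline(registry)
flip_events(timeline)
```

## The bundled CML registry

The structural transcription (24 trials, publication years, 53 arms, 17
canonical regimens) follows the published trial table; the extracted table
text lost its year column, so years were reconstructed from the narrative
anchors (first trial 1968, the IRIS trial introducing imatinib in 2003,
TKI trials 2010–2012) and the table's chronological ordering. Per-arm
enrollments and per-comparison verdicts are **not** printed in that table:
the shipped annotation overlay is synthetic, says so in its header, and was
hand-tuned once so the valued timeline mirrors the narrated eras — busulfan
overturned in 1994, hydroxyurea in 1995, the imatinib era from 2003,
imatinib overturned by dasatinib/nilotinib in 2010. Structural statistics
(trial, regimen, degree, and connectivity counts) depend only on the
printed structure; valuations and flip years depend on the synthetic
overlay and document the phenomenon, not the unpublished source data. For
the same reason the registry's patient total is not expected to match the
published ~9700 enrollment figure. The structure file is frozen by checksum
in the tests.

## The synthetic generator

`generate_trials()` emulates the registry the method assumes: yearly trial
arrivals (Poisson or fixed count), 2–4 arms, log-normal per-arm enrollments
(median 150, floored at 10 — typical of the CML trials' scale), outcome
classes drawn per comparison, and verdicts driven by latent regimen
qualities: a comparison is decisive with probability `p_decisive`, the
higher latent quality wins, and `verdict_noise` inverts the winner. This
gives recoverable ground truth: with noise-free decisive verdicts on a
round-robin pairing (all pairs cycled deterministically, so opposition is
balanced), the final value ranking recovers the latent quality ranking
perfectly — checked at 10 regimens × 100 trials. What the generator does
*not* emulate: publication bias, correlated endpoints within a trial,
heterogeneous populations, and effect-size magnitudes (the win/lose/tie
schema deliberately discards magnitude). Passing recovery tests therefore
show the scoring machinery is faithful to its own model, not that the model
resolves those real-data complications.

```{r}
cfg <- synthesis_config(n_regimens = 10, years = c(2000L, 2009L),
                        trials_per_year = 10, count_model = "fixed",
                        pairing = "round_robin", p_decisive = 1, seed = 7)
glance(quality_recovery_report(generate_trials(cfg)))
```

## Layout and rendering

Snapshots are placed with the Kamada-Kawai force-based algorithm (igraph's
implementation) under a fixed seed; yearly frames warm-start from the
previous year's coordinates, with vertices new that year seeded near the
warm-start centroid, so consecutive frames are visually stable — the
published workflow's manual touch-up of layouts is deliberately replaced by
this reproducible mechanism. The SVG writer emits one `circle.node` per
vertex and one `path.edge` per edge (parallel edges as symmetric quadratic
arcs), with `fill-opacity`/`stroke-opacity` written from the model alphas —
which is what makes the rendering machine-checkable. PNG output mirrors the
same encoding via base graphics. Frame sequences share a global bounding
box; any external encoder can assemble them into a movie. Problem sizes
throughout the examples and tests are the bundled registry (45 snapshots,
17 vertices, 40 edges) and generator runs of ≤100 trials.

## Known limitations

* No indirect-comparison adjustment: a regimen's value reflects only direct
  contests; fading is the only mechanism that demotes long-unstudied
  regimens, and it will also fade regimens whose superiority is simply
  settled.
* One annotation per trial pair (the dominant reported endpoint); trials
  reporting both a surrogate and survival are reduced to one contest.
* Win/lose/tie discards effect magnitude and confidence intervals.
* Annual resolution; no retraction or removal of evidence.
* Toxicity, cost, and comparative-effectiveness data are out of scope.
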