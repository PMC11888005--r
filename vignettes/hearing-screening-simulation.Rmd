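---
title: "Simulating hearing screenings: models, protocol logic and design choices"
author: "hearscreen authors"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hearscreen)
```

`hearscreen` is a headless simulation engine for training the abbreviated
hearing-screening protocol used by speech-language pathologists, school
nurses and other screeners. This vignette is the package's own account of
the science it implements: the clinical procedure being simulated, the
behavioural and classification models, the parameters that matter and their
defaults, what the synthetic patients do and do not capture, and the design
choices made where the design was genuinely open.

## The screening procedure

A hearing *screening* differs from diagnostic audiometry. A diagnostic test
hunts for the exact threshold — the lowest level the subject reliably
hears — at each frequency. A screening asks one binary question per ear:
does the subject respond at a single fixed level regarded as normal
hearing? The engine encodes the conventional protocol:

* **Screening level**: 20 dB HL (configurable; `protocol.json`).
* **Required frequencies**: 1000, 2000, 4000 Hz per ear.
* **Procedure order**: otoscopy, then tympanometry, then pure-tone
  screening.
* **Outcome vocabulary**: ears *pass* or are *referred* — "fail" is never
  used — and the final disposition is `pass`, `refer_audiologist` (hearing
  concern), `refer_physician` (medical concern) or `refer_both`.

The simulated device is deliberately a superset of the protocol, the way a
commercial combination audiometer is: six frequencies (250–8000 Hz) and
levels from −10 to 90 dB HL in 5 dB steps are selectable, so a trainee can
press wrong buttons and the compliance auditor can notice.

## Virtual patients and ground truth

A *base patient* carries the full per-ear ground truth: an audiogram
(thresholds in dB HL by frequency), a tympanogram (peak presence, peak
pressure in daPa, static compliance in mL, equivalent ear canal volume in
mL) and a categorical otoscopic finding, plus a case-history template and a
clinical explanation used verbatim in debrief feedback. The correct results
are *derived*, never stored, so a roster author cannot make them
inconsistent with the profiles:

* **Otoscopy** is normal exactly when the finding category is
  `clear_normal`.
* **Tympanometry** is classified by the standard screening typology:
  type B when the trace has no peak; type C when the peak pressure is below
  the normative minimum (−150 daPa by default); otherwise A, As or Ad as
  the static compliance falls within, below or above 0.3–1.5 mL. For
  referral purposes only B, C, or an ear canal volume outside the age
  band's range (child 0.4–1.0 mL, adult 0.6–2.0 mL) count as abnormal —
  shallow and deep peaks are reported but, at screening, not referred on
  their own.
* **Audiometry** is *refer* for an ear exactly when any required
  frequency's threshold exceeds the screening level. The tie goes to the
  subject: a threshold is by definition the lowest audible level, so a
  20 dB HL threshold passes a 20 dB HL screen.
* **Recommendation**: any otoscopic or tympanometric abnormality raises a
  medical flag, any refer ear an audiologic flag, and the 2×2 flag table
  maps onto the four dispositions.

The normative numbers above are conventional screening values, not
measurements made by this package; they live in `norms.json` so a program
using different local norms can change them without touching code.

The bundled roster has ten cases. Two are fixed points of the design — one
all-normal adult and one all-normal child, so that "everything normal" is
represented in both age bands. The remaining eight were authored to span
the pathologies a screener must recognise, with the three modalities kept
mutually consistent: occluding cerumen (flat trace, small canal volume,
mild conductive loss), bilateral otitis media with effusion (flat, normal
volume), an eardrum perforation (flat, large volume), patent PE tubes
(flat, large volume but normal hearing — tympanometry abnormal without an
audiologic referral), presbycusis, a 4000 Hz noise notch (which also
exercises the threshold-equal-to-level tie rule at 2000 Hz), a unilateral
sensorineural loss, and eustachian-tube dysfunction (type C). The roster is
representative of such case sets, not a reconstruction of any particular
one.

## Demographic randomization

To prevent trainees from memorising answers, every presentation re-skins a
base patient: a name is drawn from a 100-entry pool, the assigned sex is
the drawn name's tag (so name and sex can never conflict), the age is
jittered by a uniform integer offset of up to 10% of the base age (at least
±1 year) and clamped so the child/adult band — which drives the ECV norms —
is preserved, and the backstory template is re-rendered with the new
demographics. Template substitution is literal string replacement of named
placeholders (`{name}`, `{age}`, `{pronoun_subject}`, …), deliberately not
an expression-evaluating templater, since templates arrive from
user-editable files. With 10 bases and 100 names the distinct
(base, name) space is 1000; age and sex variation multiplies the apparent
variety further, but we report the conservative pair count.

Randomization is deterministic in `(base, pool, seed)` and touches nothing
clinical; both properties are enforced by tests that compare the clinical
sub-records structurally across more than a hundred seeds.

## The response model

The subject's hand-raise is a Bernoulli draw with probability

$$P(\text{respond}) = g + (1 - g - l)\,
  \frac{1}{1 + e^{-(L - t)/s}}$$

with presentation level $L$ and threshold $t$ in dB HL, slope $s$ in dB,
guess rate $g$ (false alarms) and lapse rate $l$ (missed audible tones),
constrained to $s \ge 0$, $g, l \in [0, 1)$, $g + l < 1$. At $s = 0$ the
model degenerates to a step listener: respond iff $L \ge t$, else respond
with probability $g$. The logistic is the standard psychometric form; it is
monotone in level and converges to the step model as $s \to 0$, both of
which are property-tested.

Defaults are $s = g = l = 0$: most virtual patients are perfectly
consistent, which keeps training sessions interpretable. One bundled case
(the unilateral-loss child, `p09`) uses $s = 3$ dB to emulate the
near-threshold inconsistency real subjects — children especially — show.
The magnitude is illustrative: with the case's thresholds at 40 dB HL or
worse against a 20 dB HL screen, the response probability at screening
level is below $10^{-3}$, so the stochastic behaviour is visible in
repeated presentations without ever flipping the protocol-level outcome.
Crucially, ground truth is always derived from thresholds, never from
simulated draws, so grading is stable no matter how inconsistent the
subject behaves.

Each session owns a private seeded random stream (isolated from R's global
generator), which is what makes scripted sessions and event-log replays
bit-for-bit reproducible.

## Sessions, the event log and replay

A session is a small state machine mirroring the device front panel: mode,
ear, level and frequency selections, exam buttons, tone presentation, notes
entry. Every operation appends a timestamped event; `tone_presented` events
record ear, frequency, level and the response. Timestamps come through an
injected clock function — tests use a synthetic stepping clock — and two
durations are reported: *testing* (first examination or tone to close) and
*total* (start to close).

The log plus the seed is a sufficient statistic: `replay_session()`
re-executes the logged actions on a fresh session with the same seed and
reproduces every outcome. This is also the honesty guarantee behind the
stored records — a facilitator can re-derive everything in a debrief from
the record alone.

Sessions can be driven interactively from R or headlessly from a JSON
action script (`actions.json` format, schema bundled); the scripted path is
what the test-suite and the command line use.

## Compliance auditing

The auditor checks the event log and notes of a closed session against the
protocol and emits findings by code: `MISSING_PROCEDURE` (a modality never
run), `EAR_NOT_TESTED` (modality run but an ear skipped),
`MISSING_FREQUENCY` (an ear's tone set lacks a required frequency at any
level), `WRONG_LEVEL` (one finding per distinct off-level
ear/frequency/level set), `OUT_OF_ORDER` (procedure first-occurrences out
of protocol order — a warning, since the order's diagnostic value is
real but a reordered session is not void), and `INCOMPLETE_NOTES`. An
empty finding list *is* the definition of a compliant session. The auditor
also tallies presentations per ear/frequency/level and the number of
positive responses, the counters screening guidelines expect a facilitator
to review. Rescreen-before-refer mechanics (re-instruct and retest before
referring) are deliberately not modelled; the pass rule is single-shot
response at the screening level at every required frequency.

The one-deviation/one-finding behaviour is tested by mutation: a fully
compliant scripted session is perturbed in exactly one way for each finding
kind, and the auditor must report exactly that finding.

## Grading and reports

Seven items are graded with equal weight: the six per-ear results and the
final recommendation. Equal weighting is the neutral choice in the absence
of a published rubric; the notes' free-text comments are stored and shown
but never auto-scored, because scoring prose would require a rubric we do
not have. Missing answers are incorrect and flagged as missing, so the
score is monotone: correcting any wrong answer can only raise it. The
debrief bundles graded items (with the case explanation), compliance
findings, durations and metadata; it renders to markdown for humans and to
loss-free JSON (`report_from_json()` round-trips exactly).

Records append to a line-delimited JSON store. JSONL was chosen over a
database because it is dependency-free, diffable, and naturally
append-only — records are immutable once written and ids must be unique —
while the small storage interface would let a real deployment swap in a
database. `student_history()` and `cohort_summary()` provide the
longitudinal and cross-sectional views; per-item error rates (fraction of
sessions with each item wrong) are the cohort statistic instructors use to
spot systematically missed skills, and they are verified in tests against
brute-force recounts over planted error patterns.

## Numerical and degenerate-input choices

* Tie at `level == threshold` with slope 0: respond (a threshold tone is
  audible by definition).
* `simulate_response()` always consumes exactly one uniform draw, even at
  probability 0 or 1, so response streams stay aligned across parameter
  changes.
* A session with no examinations has testing duration 0, not `NA`.
* Partial notes are legal everywhere before grading; completeness is a
  *finding*, not an error, because an incomplete session is itself a
  teachable outcome.
* Age jitter is clamped, not re-drawn, at band edges; child ages are
  additionally floored at 3 years (below which conditioned-play screening
  of this form is not realistic) and adult ages capped at 95.
* Roster validation fails with the offending patient id and field path; a
  roster is rejected whole rather than partially loaded.

## Problem sizes in the test-suite

The bundled tests run the full scripted protocol for all ten patients,
property-test monotonicity and randomization invariance over dozens of
seeds (110 seeds for the invariance checks), verify the Monte-Carlo
response rate with 10,000 draws at the logistic midpoint, and sweep a
dense tympanogram grid of roughly 5,000 parameter combinations against an
independently coded rule table. These sizes were chosen to give the
properties real coverage while keeping the whole suite fast enough to run
on every change.

## What passing tests do and do not show

The synthetic patients emulate the *structure* of screening data — mutually
consistent modality profiles, threshold-driven responses, realistic
normative ranges — not its population statistics. No claim is made that the
roster's prevalence of pathology, the ±10% age jitter, or the single
3 dB-slope inconsistent responder match any real screening population; they
are training fixtures. Likewise the engine grades *conclusions and
procedure*, not psychomotor technique: probe placement, otoscope handling
and patient instruction — the skills an instructor assesses live — are
outside what a headless simulator can measure. Results from this package
therefore speak to protocol logic and record-keeping, and to nothing
beyond it.

## Known limitations

* No bone conduction, masking, speech audiometry or threshold-seeking
  (Hughson–Westlake) procedures; diagnostic audiometry is out of scope.
* Otoscopy is categorical with an opaque `image_ref`; no images ship with
  the package.
* The store offers no concurrency control; simultaneous writers could
  interleave. Authentication is reduced to a recorded technician name.
* Reports render to markdown and JSON only; PDF export is presentation
  layer left to the caller.
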