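# hearscreen

`hearscreen` is a headless, scriptable simulation engine for teaching
hearing-screening technique to speech-language pathology and nursing
students. It stands in for supervised practice with a combination
audiometer/tympanometer when equipment or practicum time is scarce: the
trainee screens a *virtual standardized patient* whose per-ear ground truth
is known, and the engine grades their conclusions, audits their technique,
and keeps a longitudinal record.

## What it simulates

A **hearing screening** is a fixed-level pass/refer test, distinct from
diagnostic audiometry: tones are presented at a single level considered
normal hearing (20 dB HL) at 1000, 2000 and 4000 Hz in each ear, preceded by
otoscopy (visual canal/eardrum exam) and tympanometry (eardrum mobility,
middle-ear pressure in daPa, ear canal volume in mL). Per ear:

- otoscopy is *normal*/*abnormal* from the categorical finding;
- the tympanogram is typed **A/As/Ad** (peak present; compliance within /
  below / above the 0.3–1.5 mL normative range), **B** (flat) or **C**
  (peak below −150 daPa), and is *abnormal* for screening when it is B, C,
  or the canal volume leaves the age band's range;
- audiometry is *refer* when any required frequency's threshold exceeds the
  screening level (a threshold exactly at 20 dB HL is audible and passes).

Any otoscopy/tympanometry abnormality raises a *medical* flag, any failed
pure-tone screen an *audiologic* flag, and the (medical, audiologic) pair
maps to the final recommendation: `pass`, `refer_audiologist`,
`refer_physician` or `refer_both`.

The subject's hand-raise behaviour follows a guess/lapse-adjusted logistic
psychometric function

  P(respond | level L, threshold t) = g + (1 − g − l) · logistic((L − t)/s)

which reduces to a deterministic step listener at slope s = 0 (the default);
one bundled case uses s = 3 dB to emulate the threshold inconsistency real
subjects show.

Ten base patients ship with the package (one all-normal adult, one
all-normal child, and eight pathology cases: occluding cerumen, otitis media
with effusion, eardrum perforation, patent PE tubes, presbycusis, a noise
notch, a unilateral sensorineural loss, and eustachian-tube dysfunction).
Each presentation draws a name (with matching sex tag) from a 100-entry
pool and jitters the age within the child/adult band, giving ≥ 1000 distinct
(patient, name) guises over the same ten ground truths. All configuration is
plain JSON (`inst/extdata/`, schemas under `inst/extdata/schemas/`), so new
patients, protocols and norms can be added without touching code.

## A worked session

```r
library(hearscreen)

roster <- load_roster()                       # 10 bundled patients
pool   <- load_names()                        # 100-name pool
count_profile_space(roster, pool)
#> [1] 1000

pres <- randomize_presentation(roster[["p01"]], pool, seed = 42)
pres$display_name
#> [1] "Grace Thompson"

s <- start_session("Student A", pres, seed = 42, clock = step_clock())
run_actions(s, load_actions(hss_file("actions_demo.json")))
rep <- debrief(s)
glance(rep)[, c("base_id", "score", "n_correct", "n_findings")]
#> # A tibble: 1 × 4
#>   base_id score n_correct n_findings
#>   <chr>   <dbl>     <int>      <int>
#> 1 p01         1         7          0
```

The score is the fraction of 7 graded items (otoscopy, tympanometry and
audiometry per ear, plus the final recommendation) matching the ground
truth; `n_findings = 0` means the scripted session was fully
protocol-compliant (all three procedures, both ears, every required
frequency at 20 dB HL, in order, with complete notes). `render_report(rep,
"markdown")` prints the facilitator debrief; records append to a JSONL
store queried with `student_history()` and `cohort_summary()`.

The same engine is available from a shell:

```sh
Rscript inst/cli/hss list-patients
Rscript inst/cli/hss run --student "Student A" --seed 42 --patient p01 \
    --actions "$(Rscript -e 'cat(hearscreen::hss_file("actions_demo.json"))')" \
    --store sessions.jsonl --out-dir reports
# -> score 1.000 (7/7); 0 compliance finding(s); record 20240101...
```

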