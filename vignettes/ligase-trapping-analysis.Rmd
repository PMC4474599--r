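---
title: "Analysis of ligase-trapping IP-MS screens with ligasetrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of ligase-trapping IP-MS screens with ligasetrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligasetrap)
```

## The experimental design this package analyses

A *ligase trap* is an F-box protein (the substrate-binding adaptor of an
SCF ubiquitin ligase) fused to ubiquitin-associated (UBA) domains, so
that the ligase retains its polyubiquitinated substrates long enough to
co-purify them. A trapping screen purifies the trap several times,
alongside negative-control purifications with unrelated F-box traps, and
identifies co-precipitating proteins by mass spectrometry. The data that
reach this package are *total spectral counts* (TSC): the number of
MS/MS spectra assigned to each protein in each purification, a
semi-quantitative abundance proxy. Peptide-level identification
filtering (unique-peptide and FDR thresholds) is assumed to have been
applied upstream by the search pipeline; `ligasetrap` deliberately
starts from the summarized count matrix.

`ligasetrap` covers the downstream analysis end to end:

1. **Candidate calling** (`call_candidates()`) — the replicated
   presence/absence rule with family exclusion groups.
2. **Enrichment and abundance scoring** (`enrichment_score()`,
   `nsaf()`).
3. **Phosphodegron scanning** (`scan_degrons()`, `best_degron()`,
   `compare_orthologs()`) for the relaxed βTRCP consensus.
4. **Decay kinetics** (`fit_halflife()`, `stabilization_ratio()`) for
   cycloheximide-chase densitometry.
5. **Validation tallies** (`tally_validation()`,
   `compare_conditions()`, `ip_background_fraction()`).
6. **Synthetic data** (`simulate_ipms()`, `generate_sequences()`,
   `simulate_decay()`) with known ground truth.

## The candidate-calling rule

A protein is a candidate substrate when it is identified (TSC ≥
`presence_threshold`, default 1) in at least `min_bait_runs` (default 2)
bait purifications **and** in none of the negative-control
purifications. The rule is deterministic presence/absence, not a
probabilistic interaction score: with a handful of replicates and a
binary control criterion, the transparent rule is also the reproducible
one. Probabilistic contaminant models (SAINT- or CompPASS-style) are a
deliberate non-goal.

Families whose members share peptides (HLA class I alleles being the
canonical case) are handled by *exclusion groups*: if any member of a
group is detected in a control run, every member is excluded and the
reason is recorded in the `excluded_reason` column. The groups are
user-supplied because the behaviour is defined operationally, by which
peptides the search engine can distinguish, not by anything in the count
matrix itself.

Two supporting scores are computed:

* **Enrichment** — mean TSC across bait runs divided by mean TSC across
  all control runs. A zero background mean is replaced by a
  `pseudocount` (default 0.5, half the smallest observable count) so
  that proteins unique to the bait get a large finite score; setting
  `pseudocount = 0` flags them as infinite instead, for exact
  "unique to bait" bookkeeping. All control runs are pooled into the
  background average by default; per-condition backgrounds are available
  by filtering the run metadata.
* **NSAF** — the normalized spectral abundance factor,
  $\mathrm{NSAF}_i = (\mathrm{SpC}_i/L_i) / \sum_j \mathrm{SpC}_j/L_j$,
  reported ×10⁵ for readability. Per run, the values of counted proteins
  sum to 10⁵ by construction; the test suite checks this conservation on
  a thousand random tables.

`rank_candidates()` orders calls by descending total bait TSC, breaking
ties by enrichment then protein id — the ordering used for discovery
tables.

## The degron model

The βTRCP phosphodegron consensus is DpSGX(1–4)pS, with acidic residues
able to substitute for phosphoserine. The scanner's window is
`p1 p2 [G] spacer(1–4) p_last` with per-residue weights:

| position | residues (weight) |
|---|---|
| p1 | D (1.0), E (0.8), S (0.6), T (0.6) |
| p2 | S (1.0), T (0.9), D (0.8), E (0.8) |
| 3 | G (×1.0), any other residue (×0.5, multiplicative) |
| spacer | any 1–4 residues; +0.05 per D/E/S/T, capped at +0.2 |
| p_last | as p2 |

The score is `(w_p1 + w_p2 + w_plast + bonus) × w_pos3`, bounded by
3.2. Because no numeric degron score is standard in the field, the
weights are this package's construction, chosen so that the canonical
DSG…S always outranks acidic variants (DDG/SDG/SSG) and so that the
variant classes reported (`canonical_DSG`, `acidic_variant`, `relaxed`)
line up with how practitioners describe near-consensus motifs. All
weights are configurable through `degron_model()`.

Two design points deserve explanation:

* **Glycine is strongly preferred, not required.** Several
  well-documented degrons vary in this part of the motif, and at least
  one validated substrate motif (UBE4B's DTTFLLD) contains no glycine at
  all; a hard glycine gate would render such windows invisible. The
  default therefore multiplies non-glycine windows by 0.5, which keeps
  them far below any glycine-containing window while still reporting
  them as `relaxed` hits. Setting `non_glycine_weight = 0` restores a
  strict DpSGX(1–4)pS scan. Note that a *transposed* glycine (DGD…)
  still fails by default, because position 2 must be a
  phospho-acceptor/acidic residue; the optional `relaxed = TRUE` mode
  additionally accepts `p1 G p2 spacer p_last` windows for exploring
  such outliers.
* **Phospho-status is not modelled.** S/T are treated as potential
  phospho-acceptors on the unmodified sequence, because scanning is done
  on plain FASTA records.

`best_degron()` picks the highest-scoring window per protein, breaking
ties by smaller spacer and then smaller start — a compact window earlier
in the sequence is reported when scores are equal. Overlapping windows
are all reported by `scan_degrons()`, since an extended acidic stretch
can legitimately contain two overlapping near-consensus degrons and the
choice between "one extended degron" and "two overlapping ones" is a
matter of interpretation, not of the scan.

`compare_orthologs()` locates the reference species' best window in each
ortholog by sliding the window (with 5 residues of flanking context)
along the ortholog and maximizing identity — alignment-free by design,
since a 5–8 residue window does not support a meaningful alignment — and
reports per-position identity fractions across species.

## Decay kinetics

Chase densitometry is normalized by the loading control and anchored to
1 at time zero, then fitted by least squares on log(intensity) versus
time inside a stated window (default 0–2 h, the early log-linear phase
of a chase). A log-linear fit, rather than a nonlinear exponential fit,
matches how chase half-lives are conventionally read off the linear part
of the timecourse; nonlinear refinement is out of scope. Numerical
choices:

* points with intensity ≤ `floor` (default 0.01) are excluded with a
  warning — the log of a near-zero band quantitation is dominated by
  background subtraction noise;
* the rate is clipped at 0 and fits with k ≤ `k_min` (default 0.01 /h,
  i.e. a nominal half-life beyond ~70 h, far outside any chase) are
  flagged stable with an infinite half-life;
* `r_squared` is taken from the same regression, and defined as 1 for a
  perfect (zero-residual) fit even when the response is constant.

`stabilization_ratio()` maps the treated/reference half-life ratio onto
the yes/partial/no vocabulary used in validation tables, with defaults
of 2.0 (full) and 1.3 (partial). Published labels of this kind are
assigned by inspection of blots, so the thresholds are exposed rather
than hard-coded; a treated fit flagged stable yields the class
`"stable"`. `translation_recovery_ratio()` is purely arithmetic lane
normalization for puromycin-incorporation (SUnSET-style) densitometry.

No numeric half-life is asserted against published values anywhere in
the package: published chase results are graphical, so this module's
guarantees are property-based (exact recovery on noiseless exponentials;
median rate error ≤ 15% at 5% multiplicative noise with four points in
0–2 h, measured over 100 simulations).

## Validation tallies

`tally_validation()` counts known substrates, confirmed novel
substrates (polyubiquitinated forms purified by the trap — stability
results do not enter the criterion), false positives, and untested
candidates. The confirmation rate removes untested candidates from the
denominator: a candidate that could not be examined is evidence of
nothing. Percentages are rounded half away from zero for display and
retained unrounded in `*_exact` columns. The packaged fixture
(`load_table1_fixture()`) reproduces a published 28-candidate βTRCP
screen — 12 known, 11 confirmed novel, 3 false positives, 2 untested,
an 88% confirmation rate and a 43% previously-published fraction —
and `reproduce_table1()` recomputes all of it from the counts up.
The fixture also carries four "below-bar" known substrates that were
control-detected; `table1_calling_table()` reconstructs that detection
regime with synthetic control runs (zeros for candidates, ≥1 count for
below-bar rows), since the printed table contains bait counts only.

## What the simulator emulates — and what it does not

`simulate_ipms()` draws substrate counts from Poisson distributions with
per-run dropout, sticky-background proteins from Poisson in every run,
and leaves the rest at zero. Defaults (500 proteins, 5% substrates,
λ_substrate = 8, λ_background = 3, 20% sticky, 10% dropout, 3 bait + 2
control runs) describe a modest trapping screen: mean substrate counts
below ten match the low end of real discovery tables, where two-of-three
detection patterns like (3, 3, 0) or (1, 1, 0) are common, and the
dropout parameter is what produces them. The 100–2000 residue uniform
length range is a realistic proteome span for NSAF. Poisson rather than
negative binomial is the default for transparency — no published
count-noise model exists for this assay — and the simulator's simplicity
is the point: it provides exact ground truth, not realism.

Features of real data the simulator does *not* emulate: substrate
leakage into controls (simulated substrates are exactly absent from
control runs, matching the calling rule's regime, so the control-absence
branch of the rule is exercised by the sticky class only), peptide
shared-identification artifacts (HLA-type families), run-to-run
normalization differences, and correlated replicate noise. Passing tests
on simulated data therefore demonstrate the correctness of the
*computations*, not the field performance of the rule on any particular
instrument or search pipeline.

`generate_sequences()` writes planted motifs verbatim into random
backgrounds in which D/E/S/T are down-weighted (relative weight 0.3), so
spurious degron-like windows are rare but not impossible — tests assert
on top-ranked hits, which is the property that matters for
`best_degron()`.

## Problem sizes and determinism

The test suite runs everything at small scale: oracle equivalence on
150 random 60-mers plus 1000 random ≤60-mers in the end-to-end checks,
1000 random NSAF tables, 100-seed half-life recovery, and one simulated
500-protein screen. These sizes give stable pass/fail behaviour at
negligible cost; all stochastic tests fix their seeds, and
`simulate_*()` functions are bit-reproducible given a seed. Every
empirical number quoted in this vignette or the README is computed by
the test suite or by `scripts/acceptance.R`.

## Known limitations

* The calling rule is sensitive to the control set: a single spurious
  control spectrum vetoes a protein. That is faithful to the
  presence/absence design, but users with many controls may prefer
  raising `control_presence_threshold`.
* The degron score is a heuristic ranking device, not a calibrated
  binding-affinity model; scores are comparable between windows, not
  between unrelated proteins.
* The ortholog comparison assumes the degron's neighbourhood is locally
  conserved enough for identity-based placement; for deep divergence a
  proper alignment tool is the right choice.
* Decay fitting assumes first-order kinetics within the window; biphasic
  decays (stable and unstable pools of one protein) show up as reduced
  r², not as a two-component fit.
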