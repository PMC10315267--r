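---
title: "Calling time-of-day-specific protein interactors from APMS spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling time-of-day-specific protein interactors from APMS spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoprot)
```

## The problem

Circadian clock proteins do different things at different times of day, and
so do their binding partners. Affinity-purification mass spectrometry (APMS)
makes that visible: a tagged bait protein is purified from tissue harvested
at chosen Zeitgeber times (ZT, hours after lights-on), and every
coprecipitated protein is identified and semi-quantified by its total MS/MS
spectral count per run. Purifying the same bait at two times of day and
comparing the interactor lists separates all-day partners from
time-restricted ones — in the motivating experimental design, MYB-like
transcription factor baits and their coactivators purified at ZT5 and ZT9,
where cold-response regulators appear only in the evening pull-downs.

`chronoprot` implements that comparison as a tested pipeline, together with
the downstream analyses such a study needs: circadian period and acrophase
estimation for luciferase reporter traces, circular statistics, entrainment
resynchronization testing, western-blot densitometry and dual-luciferase
normalization, flat-annotation term enrichment, and affine-gap global protein
alignment. A synthetic-data module generates every input class with known
ground truth.

## Interactor calling

The calling pipeline consumes a proteins x runs matrix of total spectra with
run metadata (bait, ZT, replicate, control flag) and applies, in order:

1. **Evidence filtering** (`apply_evidence_filter()`). Identifications are
   trusted upstream software for peptide/protein probabilities; when a
   peptide-level table is supplied, peptides are kept at probability > 0.95
   with local FDR < 1% and proteins at probability > 99.9%, and unique
   peptides are recounted per run. A protein is retained in a bait x
   timepoint group when some replicate has at least 2 unique peptides, or a
   single peptide is seen in more than one replicate of the group. The rule
   is applied per group, because replicate evidence only accumulates within
   an experiment; negative-control identifications are deliberately exempt,
   so that even one-spectrum control hits remain visible to the next stage.
   The packaged curated tables carry total spectra only — they are
   post-threshold exports — so on them this stage is a documented no-op.
2. **Control subtraction** (`subtract_controls()`). Any protein with at least
   one spectrum in any negative-control purification (tag-only or
   untransformed background) is removed everywhere. The exclusion is
   presence-based, not quantitative: sticky background proteins are not
   rescued by high bait counts. This mirrors curated-table practice and makes
   the operation idempotent.
3. **Interactor calls** (`call_interactors()`): per bait x timepoint, every
   remaining protein with a spectrum in at least one replicate, reported with
   per-replicate counts, sorted by descending maximum spectra then locus.
4. **Timepoint classification** (`classify_timepoints()`): loci are pooled
   across baits within each timepoint and partitioned into `early_only`,
   `late_only` and `shared`; per-bait partitions are kept alongside.
   Classification keys on the AGI locus, never the display name — the same
   locus can be annotated under different protein names in different
   experiments.

Proteins indistinguishable by peptide evidence can be grouped beforehand with
`group_by_parsimony()`: identical peptide sets merge, strict subsets are
absorbed by their superset protein, and non-nested overlap links proteins
into a common cluster without merging their identities.

```{r fixtures}
t1 <- load_table_fixture("table1") # three baits at ZT5
t2 <- load_table_fixture("table2") # the same baits at ZT9
baits <- c("LNK1HFC", "LNK2HFC", "RVE8HFC")
cls <- classify_timepoints(
  lapply(baits, function(b) call_interactors(t1, b, 5)),
  lapply(baits, function(b) call_interactors(t2, b, 9))
)
glance(cls)
```

On the packaged curated tables this yields 41 pooled loci, 10 of them
evening-specific — including the two cold-regulated proteins, plus the
photomorphogenesis E3-ligase components, that motivated the design — while
the two RCC1-family proteins are called at both timepoints.
`cycling_fraction()` cross-references any locus set against a cycling-gene
map; `enrich_terms()` performs one-sided hypergeometric enrichment against a
flat annotation. The enrichment background defaults to all proteins detected
across runs before filtering, the conservative detected-proteome choice; raw
p-values are reported by default with Benjamini-Hochberg correction behind a
flag, and no ontology-graph propagation is attempted (annotations are
consumed as a flat map).

## Rhythm analysis

`fit_fft_nlls()` estimates period, amplitude and acrophase by Fourier-seeded
nonlinear least squares. The model is
$y(t) = c + d\,t + \sum_i A_i \cos\!\big(2\pi (t - \phi_i)/\tau_i\big)$:
a linear trend plus up to `max_components` cosines. Candidate periods come
from the zero-padded periodogram of the linearly detrended trace, restricted
to the search window (default 15–35 h, bracketing plausible plant circadian
periods); the fit itself uses variable projection — for fixed periods the
trend and cos/sin coefficients are solved in closed form, and only the
periods are optimised numerically. Components are added while an F-test on
the residual sum of squares is significant at $\alpha = 0.05$. Each
component's relative amplitude error (RAE) is the half-width of its 95%
amplitude confidence interval (from the linearised covariance at the
optimum) divided by the amplitude; the in-window component with the smallest
RAE is reported and the trace is called rhythmic when RAE < 0.6. These
internals follow common practice for FFT-NLLS implementations, but the exact
component-acceptance and RAE conventions of the classic desktop tools are
not published; this package's formulation is therefore its own, fixed by the
contracts above and the tests, with every constant configurable. A constant
trace returns `rhythmic = FALSE` rather than an error; traces shorter than
twice the minimum period are refused.

Acrophase (time of daily peak) extraction (`daily_acrophase()`) smooths with
a centred moving average (default 3 h) and takes the per-cycle maximum in
consecutive windows anchored at the condition-segment start. Sampling is
treated as exactly hourly; small acquisition gaps around lights-off are
ignored. `rayleigh()` summarises phase agreement with the mean resultant
length R and the standard large-sample significance approximation
$p = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n)\big)$, $R_n = nR$.
`compare_periods()` wraps one-way ANOVA with Tukey's HSD and a compact
letter display. `compare_acrophases()` tests each genotype against a
reference per entrainment day with Welch's t-test after unwrapping that
day's phases into the reference's half-cycle neighbourhood — day-level tests
are linear after local unwrapping, matching how such acrophase series are
usually plotted with linear error bars; fully circular two-sample tests are
out of scope. The resynchronization day is the first day from which all
subsequent tested days are non-significant, `NA` when alignment is never
reached.

## Quantification

`normalize_blot()` implements standard densitometry algebra: with 8-bit
inverted gray values (the inversion constant is configurable but bit depth
is rarely anything else for exported blot scans), net density is background
ROI minus band ROI, band net is divided by the loading-control net, and each
(genotype, biorep) series is rescaled to max = 100, so a single-lane biorep
is 100 by construction. Lanes with non-positive loading net are an error:
they indicate a quantification problem, not a value of zero.

`dualluc_fold_change()` computes per-reading firefly/renilla ratios after
plate-background subtraction (the renilla channel absorbs infection
efficiency), normalizes by the no-effector ratio — per leaf when `leaf_id`
is present, because each leaf carries its own no-effector quadrant, else per
experiment — and compares combinations by Welch's t-test. The no-effector
fold is 1 by construction. Readings with non-positive net renilla are
excluded with a warning. `welch_t()` itself delegates to the standard Welch
test with Satterthwaite degrees of freedom, hardened so the degenerate
zero-variance limits return `p = 1` (identical samples) or `p = 0`
(separated constants) instead of erroring.

## Protein alignment

`global_affine_align()` is a three-state (Gotoh) affine-gap global aligner
with EMBOSS-needle default semantics: BLOSUM62, gap open 10, extension 0.5
per gap position (a gap of length $L$ costs $10 + 0.5L$), terminal gaps free
unless requested otherwise, and percent identity computed over the full
alignment length including gap columns. Traceback ties are resolved
deterministically (aligned pair, then gap in the first sequence); the score
is tie-break-invariant, which the tests exploit by checking scores against
an exhaustive enumeration of all alignments and against an independent
implementation. The dynamic program is compiled (Rcpp), so full-length
protein pairs align in well under a second.

## Synthetic data and what the tests do (and do not) show

`simulate_apms()` plants a known interactome: negative-binomial spectral
counts (dispersion 0.5 — overdispersion is the norm in spectral counting)
for each planted prey in the runs of its bait whose ZT falls inside the
prey's expression window, sticky gamma-distributed background proteins in
bait and control runs alike, and unique-peptide counts that grow with
spectra. Two guarantees are enforced so that recovery is exact by
construction: every planted interactor receives spectra (and
evidence-passing peptide support) in each in-window group, and every
background protein appears in at least one control run. Under those
guarantees the pipeline's planted-interactor recall is 1 and background
survival is 0 across seeds — a consistency check of the filtering logic,
not a statement about sensitivity on real data, where low-abundance
interactors can genuinely fall below detection and background proteins can
evade the controls.

`simulate_traces()` generates a free-run segment (damped cosine at the
genotype's period) followed by an entrainment segment in which the acrophase
offset from the entrainer target shrinks linearly by a per-day relock rate,
with multiplicative Gaussian noise. The linear pull is a deliberate
caricature — a real oscillator relocks through its phase-response curve —
but it exercises the acrophase/resynchronization pipeline with analytically
known truth. Defaults emulate the motivating design: a wild-type-like
genotype (24.6 h, fast relock) and a mutant-like one (26.5 h, 6 h initial
offset decaying 2 h per day, hence resynchronization on day 3), 16 plants,
hourly sampling, temperature-entrainment labels in either nonramping (step)
or ramping flavour.

`simulate_quant()` emulates a blot time course whose protein peaks sharply
at ZT6 and is degraded by evening, with a mutant that stabilises the protein
(default x2) from ZT9 onward — the low evening baseline keeps the biorep
maximum at ZT6, so the max = 100 normalization leaves morning timepoints
untouched and only the stabilised evening timepoints are flagged (morning
flags appear at the type-I rate, about 5%). The dual-luciferase arm applies
multiplicative effector effects (activation 3x, corepressor-damped 1.5x)
under 10-fold per-leaf infection-efficiency variation that cancels exactly
in the firefly/renilla ratio.

## Numerical and design notes

* Problem sizes in the shipped tests and acceptance script: traces of 120 h
  at hourly sampling; 20-seed damped-cosine recovery; 10^4-replicate null
  simulations for the Welch and ANOVA sizes; 100-seed planted-APMS runs;
  alignment-oracle checks on all pairs up to length 2 over a 4-letter
  alphabet plus a seeded sample of longer pairs (exhaustive enumeration
  grows like the Delannoy numbers, so sampling is the honest scale for the
  oracle).
* The curated fixture tables reproduce the printed source tables exactly
  (one run-header typo normalised so all four replicate columns of one bait
  parse to the same bait); they ship without unique-peptide columns, so
  evidence filtering on them is a no-op by contract.
* Tie-breaks are fixed everywhere output order matters: interactor tables
  sort by descending maximum spectra then locus; alignment traceback prefers
  an aligned pair over gaps.
* Degenerate inputs have defined behaviour rather than errors where a
  pipeline consumer benefits: constant traces are arrhythmic, flat acrophase
  windows are flagged `NA`, zero-variance group comparisons return the
  analytic limit.
* The Rayleigh p-value approximation is accurate for n of a few and
  conservative near R = 0; it is an approximation, not an exact permutation
  p.
* Known limitations: no probabilistic interaction scoring (counts are
  filtered, not modelled against controls quantitatively); no
  ontology-graph-aware enrichment; no wavelet or Lomb-Scargle alternatives
  for unevenly sampled traces; densitometry starts from ROI mean gray values
  and trusts equal ROI areas upstream.
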