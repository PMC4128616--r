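---
title: "Electropherogram-based purity screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electropherogram-based purity screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puritrace)
```

## The screening problem

Establishing unialgal cultures from an environmental sample usually ends
with a verification step: does the isolate really contain a single strain?
Microscopy catches gross contamination but not congeners of similar
morphology. Sequencing a variable marker — here the V4 region of the 18S
rRNA gene, amplified with the eukaryote-universal pair TAReuk454FWD1 /
TAReukREV3 — gives a molecular answer, but a mixed culture does not
produce an obviously "wrong" sequence; it produces a *superimposed*
electropherogram. Wherever the co-amplified templates differ, two dye
channels peak at comparable height at the same scan position. The base
caller must still emit one call, its error probability `Pe` rises, and the
Phred quality value `QV = -10 log10(Pe)` falls, often to single digits.

`puritrace` turns that observation into a classifier: after an objective
quality trim, the fraction of retained calls with QV strictly below 20 is
compared against a strict 1% bound. Below the bound the culture is called
`unialgal`, otherwise `mixed`. Reads with no acceptable 5' window at all
are reported `indeterminate` rather than silently classified — in
practice these are either failed sequencing reactions or mixtures of
templates with a length polymorphism, where a one-base shift scrambles
every downstream call and no 20-base window stays clean.

## The two-rule trim

Both classification and trimming operate on the same per-base QVs.
Comparisons are strict everywhere, mirroring how the thresholds are
stated: "QV above 20" excludes QV 20 in the 5' rule, and "below QV 20"
excludes QV 20 in the 3' rule and in the purity statistic. All internal
coordinates are 0-based half-open; report tables are 1-based inclusive.

**5' rule.** With defaults `head_skip = 25`, `window = 20`,
`qv_threshold = 20`: the retained read starts at the smallest position
`s >= head_skip` such that all `window` calls starting at `s` are strictly
above the threshold. The initial skip exists because the first ~25 bases
of a Sanger read are unreliable for every sample (primer-proximal noise),
so a clean window there would be accidental. The skip is exposed as a
parameter because routine practice treats 25–35 as operator latitude; a
single deterministic default keeps batch results reproducible. Two
boundary decisions were genuinely open and are resolved as follows:

* "20 consecutive calls above threshold" is read as *all* calls in the
  window, not a window mean — "consecutive" only makes sense as a
  per-call requirement.
* A window truncated by the read end (starting at or after `head_skip`,
  running to the last base, at least one base long) still qualifies. A
  short but uniformly clean read is thus trimmed rather than rejected;
  rejecting it would discard exactly the reads easiest to assess.

If no window qualifies, the result is `failed_head` — a value, not an
error, and downstream a `indeterminate` classification.

**3' rule.** With defaults `tail_scan_start = 350` and
`max_bad_in_window = 1`: scanning windows that start at least 350 bases
past the 5' trim point, the read ends immediately before the first window
holding more than one call below the threshold. The offset is counted
from the 5' trim point, not the raw read start: the two rules are
sequential operations on the read, and counting from the trim point is
what yields the useful guarantee that any read extending 350 bases past
its start retains *at least* 350 bases — a floor that keeps even noisy
mixed-template reads long enough for a stable purity fraction. Windows at
the 3' end must fit entirely; if quality never degrades, the read is kept
to its end (the rule describes where to cut, not an obligation to cut).

**Purity statistic.** On the trimmed read,
`fraction = #\{QV < 20\} / retained_length`, classified `unialgal` iff
`fraction < 0.01` strictly. With 1000 retained bases the flip from
`unialgal` to `mixed` therefore happens at exactly 10 weak calls, and the
test suite pins that boundary. Percentages are reported to two decimals.
The statistic is position-blind once trimming has fixed the interval;
permutation invariance is also under test.

## The quality model and the simulator

Real instruments derive QVs from trace features with proprietary
calibration tables. For simulation-based validation the package uses a
deliberately simple monotone model over the three features that matter
for mixture detection: per base,

```
pe = clip( w_ratio * (secondary / primary)
         + w_res   * (1 - resolution)
         + w_space * spacing_dev,  pe_floor, pe_ceiling )
```

with defaults `w_ratio = 0.5`, `w_res = 0.3`, `w_space = 0.2`,
`pe_floor = 1e-4` (QV 40 cap), `pe_ceiling = 0.75`. A linear-in-features
form was chosen over a logistic one as the simplest model that is monotone
in each feature; the weights make the feature that defines a mixed base —
the uncalled/called peak-height ratio — dominant: at equal stacked peaks
(ratio 1) `pe >= 0.5`, i.e. QV <= 3, an uncallable position, while a clean
base clips to the floor. A base with a zero-height primary peak is fully
ambiguous and receives `pe_ceiling`. Any numeric agreement with a real
basecaller's QVs would be coincidental; what is relied on, and tested, is
calibration in the two regimes the classifier compares (see below).

The simulator generates the four processed channels as sums of Gaussian
peaks. Its defaults define the simulated study conditions and were fixed
once:

* **Templates** default to 600 bases (`random_template()`), so the
  350-base 3' floor is genuinely exercised; amplicon-length templates
  from `amplify()` can be used instead.
* **Peak geometry**: 12 scans/base spacing with 0.15-scan jitter, initial
  peak width 1.2 scans, peak amplitude 1000 (arbitrary units), additive
  Gaussian channel noise with sd 0.5. On processed (baseline-subtracted,
  mobility-corrected) traces the noise floor is far below peak height;
  0.05% of amplitude reproduces the high-QV plateau of a good run
  (median QV 30–31 under the quality model above).
* **5' ramp**: the first `head_ramp_len = 25` bases carry a linearly
  decaying contaminant peak on another channel, reproducing the universal
  low-quality read start that motivates the 25-base skip.
* **3' degradation**: peak width grows as
  `peak_sigma * (1 + (resolution_decay * i)^3)` with
  `resolution_decay = 0.0019`, i.e. broadening becomes severe around
  1/0.0019 ≈ 525 bases. The cubic onset matches the phenomenology of
  capillary reads — a long flat stretch followed by a fairly rapid
  collapse — and, importantly for the classifier, keeps the
  quality *transition zone* short, so a clean read accumulates almost no
  weak calls before the 3' rule cuts (typical retained length ~430 of
  600 bases at defaults).
* **Mixtures**: each template contributes, at each consensus position, a
  peak on the channel of its own base with height proportional to its
  mixing weight (idealised linear dye response). Divergent positions are
  exactly where active templates disagree; `indel_offsets` shifts a
  template's reading frame to model interspecific length polymorphism, in
  which case nearly all positions past the shift (all those where
  adjacent template bases differ, ~3/4 for random sequence) become
  divergent and the read fails head trimming.
* **Determinism**: one root seed per config; a config, including its
  seed, maps to a byte-identical `.ab1` file.

Calibration, asserted by the test suite at these defaults: clean
single-template traces have median QV >= 30 and a sub-QV20 fraction below
1% after trimming; 50:50 mixtures put every divergent position below
QV 20 with uncalled/called ratio in [0.8, 1].

**What the simulator does not emulate**: dye blobs, mobility artefacts,
polymerase slippage, chimeric amplicons, heterogeneous template-specific
peak mobilities, or any real instrument's noise spectrum and quality
tables. Passing simulation tests therefore demonstrates that the
*algorithmic chain* (trace → features → QV → trim → fraction → class)
discriminates the two regimes it models; it does not certify performance
on any particular instrument's output, where QVs come from the vendor's
own calibration and the trim/classification rules consume them as-is.

## In-silico PCR

Primer sites are matches of a degenerate IUPAC primer with at most
`max_mismatch` substitutions (degenerate positions match their code set
at zero cost; matching is delegated to Biostrings with the pattern
ambiguous and the subject literal). The default mismatch budget is 0,
consistent with clean single-band products on a gel. Products are
enumerated for both orientations of the template — a forward site whose
footprint precedes a reverse-complement reverse site, with
non-overlapping footprints — and are primer-inclusive, since gel sizing
measures the full product. No melting-temperature or 3'-anchor model is
applied; that is beyond what a site/size predictor needs here. The
bundled `synthetic_18S_V4_template.fasta` is a *synthetic* stand-in (not
a database record) whose primer sites are spaced to give the documented
421 bp diatom V4 product size.

## ABIF dialect

The writer emits a minimal big-endian ABIF: header, directory, and the
tags listed above, with data blocks of four bytes or fewer stored inline
in the directory entry as the format requires. Channel intensities and
peak positions are stored as 16-bit integers (hence validated to
[0, 32767]); qualities as bytes in [0, 93], the printable Phred range —
out-of-range values are rejected, not clamped, to fail loudly on corrupt
data. The channel-to-nucleotide mapping is honoured from `FWO_` rather
than assumed, since instruments vary. The reader requires only the
mandatory tag set and tolerates tag number 1 or 2 (which copy a
basecaller populates varies); it reports three distinct failures: missing
magic ("not an ABIF file"), missing mandatory tag ("incomplete trace"),
and internally inconsistent lengths ("corrupt trace").

## Problem sizes used in validation

The shipped tests run, among others: 10,000-read random-QV oracle
equivalence for the trimmer (reads up to 1000 bases, QVs uniform on
[0, 60]); 100 seeded pure and 100 seeded 50:50 mixed simulations for the
end-to-end discrimination claim (both directions must reach 95%); a
5-level dose-response (minor proportion 0, 0.05, 0.1, 0.25, 0.5 at 100
seeds each) whose median sub-QV20 fraction must be non-decreasing; and
100 randomised ABIF round-trips. These sizes give stable pass/fail
behaviour for properties with ≥95% rate bounds while keeping a full run
in the low minutes on one core.

## Known limitations

* The classifier sees only QVs; a contaminant identical to the dominant
  strain across the sequenced window is invisible, as is any mixture
  whose minor component falls below the trace's noise floor.
* `failed_head` reads are not further diagnosed; distinguishing "failed
  reaction" from "indel mixture" would need trace-level features the
  screen deliberately does not depend on.
* The quality model is a validation instrument, not a re-implementation
  of any vendor basecaller; QVs in real `.ab1` files should be used
  as produced by the instrument.
* Amplicon prediction counts substitutions only; primers with strong 3'
  mismatch sensitivity or unusual thermodynamics are outside its scope.
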