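# puritrace

Is this algal culture unialgal? `puritrace` answers that question from a
single Sanger sequencing electropherogram of a marker-gene amplicon —
typically the hypervariable V4 region of the 18S rRNA gene — without
cloning, replicate sequencing or manual trace inspection.

The idea: when a culture contains more than one strain, the PCR product is
a mixture of templates that differ at some positions. At every such
position the chromatogram shows two peaks of comparable height, the base
caller cannot decide, the per-base error probability `Pe` rises, and the
Phred quality value

```
QV = -10 * log10(Pe)
```

drops. A clean single-strain trace, by contrast, keeps almost all calls at
high QV. After a well-defined quality trim, the *fraction of retained
calls below QV 20* separates the two cases sharply: the culture is
classified **unialgal** when that fraction is strictly smaller than 1%.

The trim itself is the part that must be objective, and is implemented
exactly as a two-rule window scan:

1. **5' rule** — skip the first 25 bases (configurable 25–35), then start
   the read at the first position where 20 consecutive calls are all
   strictly above QV 20;
2. **3' rule** — beginning 350 bases past that start, end the read just
   before the first 20 consecutive calls that contain more than 1 call
   strictly below QV 20.

Rule 2's offset doubles as a guaranteed floor: even a noisy
mixed-template read keeps at least 350 bases, enough for a reliable
purity call.

Around this core the package provides:

- **ABIF I/O** — read and write `.ab1` trace files (channels, peak
  locations, basecalls, qualities, channel order), plus paired
  FASTA + QUAL files;
- **in-silico PCR** — degenerate-primer matching and amplicon extraction
  for the built-in eukaryote V4 pair TAReuk454FWD1
  (`CCAGCASCYGCGGTAATTCC`) / TAReukREV3 (`ACTTTCGTTCTTGATYRA`);
- **a chromatogram simulator** — mixed-template traces with known ground
  truth (divergent positions, mixing proportions, optional one-base
  length polymorphism that scrambles every downstream call), used to
  validate the whole pipeline end to end;
- **tidy interfaces** — report tables are tibbles, result objects have
  `tidy()`/`glance()` methods and `autoplot()` draws traces and reports.

## Worked example

Simulate one pure culture and one 50:50 mixture of two templates at 10%
sequence divergence, write them as `.ab1`, and screen them:

```r
library(puritrace)

t1 <- random_template(600, seed = 101)
t2 <- divergent_template(t1, divergence = 0.1, seed = 101)
cfgs <- list(
  sim_config(t1, seed = 101, id = "pure_culture"),
  sim_config(c(t1, t2), proportions = c(0.5, 0.5), seed = 102,
             id = "mixed_culture")
)
dir <- tempfile()
truth <- generate_dataset(cfgs, dir)
report <- screen_batch(file.path(dir, truth$file))
report[, c("id", "status", "retained_length", "n_subthreshold",
           "percent_subthreshold", "classification")]
#>              id  status retained_length n_subthreshold percent_subthreshold
#> 1  pure_culture trimmed             432              0                 0.00
#> 2 mixed_culture trimmed             350             34                 9.71
#>   classification
#> 1       unialgal
#> 2          mixed
```

The pure trace keeps 432 bases with not a single call below QV 20; the
mixture is trimmed back to the 350-base floor and still carries 9.7% weak
calls — far over the 1% cutoff — so it is flagged `mixed`. `glance(report)`
summarises a whole screening batch in one row.

In-silico PCR on a bundled template (a synthetic stand-in whose primer
sites are spaced like a diatom V4 amplicon):

```r
fa <- system.file("extdata", "synthetic_18S_V4_template.fasta",
                  package = "puritrace")
amplify_fasta(fa)[, c("template_id", "start", "end", "length", "strand")]
#>   template_id start end length strand
#> 1   synthetic    60 481    421      +
```

A thin command-line wrapper is installed at
`system.file("cli", "puritrace", package = "puritrace")` with subcommands
`screen`, `trim`, `simulate` and `pcr`.

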