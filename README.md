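# polfx

Correlative optical-tweezers / fluorescence analysis of DNA-polymerase
exchange at the ssDNA/dsDNA replication junction.

## What it does and who it is for

In a dual-trap assay a single DNA template is held between two beads while a
confocal line scan images fluorescently labeled DNA polymerase on it. The
trap measures force *F* and bead-to-bead end-to-end distance (EED) at 20 Hz;
the scanner produces a kymograph (position × time photon counts). Because
ssDNA and dsDNA have different elasticity, the measured EED at a given force
encodes how much of the template is single-stranded, and therefore where the
ssDNA/dsDNA junction — the site of polymerase action — sits along the
bead-to-bead axis. `polfx` turns these two raw measurements into the
statistics used to characterise fast polymerase exchange: burst segments and
their activity types, pauses, activity × fluorescence correlation classes,
the eight-configuration memory-effect distribution, bound lifetimes corrected
for photobleaching, and diffusion constants of polymerases on ssDNA and
dsDNA. It is aimed at single-molecule biophysicists with C-Trap-style
correlated force + confocal data (exported to the plain-text interchange
formats below), and ships a ground-truthed stochastic simulator so every
stage of the pipeline is testable without instrument data.

## The model

ssDNA follows an extensible freely-jointed chain and dsDNA an extensible
worm-like chain (Odijk high-force form), per full-length template:

    FJC(F) = L_ss [ coth(Fb/kT) − kT/(Fb) ] (1 + F/S_ss)
    WLC(F) = L_ds [ 1 − (1/2) √(kT/(F L_p)) + F/S_ds ]

A template with ssDNA fraction `ss` has EED = ss·FJC(F) + (1−ss)·WLC(F), so

    ss = (EED − WLC(F)) / (FJC(F) − WLC(F))                    (fraction)
    junction = ss·FJC(F) / (ss·FJC(F) + (1−ss)·WLC(F)) · EED   (position)
    bp_ds = round((1 − ss) · N_bp)                              (base pairs)

Downstream, the base-pair trace is segmented into piecewise-constant
catalytic rates (change-point fitting), rates are classified as
exonucleolysis (negative, high force), polymerisation (positive, low force)
or pause (|rate| below 10 bp/s at ≥ 40 pN, 20 bp/s at ≤ 20 pN), and the
kymograph is registered to the junction trajectory by an exhaustive ±5 px
offset search maximising the photons in a 5-pixel junction box. Bound
lifetimes are corrected for photobleaching by the competing-exponentials
identity 1/τ_obs = 1/τ_off + 1/τ_bleach; diffusion constants come from the
MSD slope (MSD = 2Dτ + b, 1-D motion along the DNA axis).

## Worked example

```r
library(polfx)
cfg <- simulation_config(seed = 1, duration = 120)   # stated-world defaults
out <- file.path(tempdir(), "demo")
run_simulate(cfg, out)                               # force CSV, kymograph TSV, truth JSON
report <- run_analyze(out, analysis_config(), out_dir = file.path(out, "analysis"))
cat(report$log, sep = "\n")
```

```
reconstruct: 2400 samples, 0 clamped, 0 flagged
register: offsets dx=0 dy=0, objective=28837
binarize: threshold=22.58 counts, 588/1200 lines fluorescent
segments: 29 total (25 single-type), 10 pauses, 24 memory-countable
correlation: clusters 11=23 10=8 01=19 00=11
lifetime: 28 usable events, 1 truncated at trace ends
tracking: 16 trajectories
```

What the numbers mean: the junction trajectory was reconstructed on all 2400
force samples with no out-of-range ssDNA fractions; registration confirmed
the coarse alignment (offsets 0,0); 588 of 1200 kymograph lines carry
above-threshold junction fluorescence; 29 maximal fluorescent runs became
burst segments, 25 of them single-activity (86%, against ~90% single-type
truth in this simulation); 10 pauses were detected; the correlation classes
[fluorescence, activity] produced 23/8/19/11 clusters of [1,1]/[1,0]/[0,1]/
[0,0], i.e. a fluorescent-event fraction of 0.51 and a non-fluorescent pause
fraction of 0.58. The bleach-corrected mean bound lifetime is 2.46 ± 0.55 s
against a configured 1.2 s dwell — an upper bound, because exchanges faster
than the ~3-line event resolution merge consecutive bindings into one
fluorescent run (the same caveat applies to the real measurement).
`run_report(report, dir)` renders a text summary and PNG panels.

The simulator's CLI mirror:

```sh
Rscript inst/cli/polfx.R simulate -c config.json -o data/
Rscript inst/cli/polfx.R analyze  -d data/ -o results/
Rscript inst/cli/polfx.R report   -r results/report.json -o figures/
```

## Interchange formats

- force trace: CSV, header `time_s,force_pN,eed_um` (EED pre-corrected for
  bead radii);
- kymograph: TSV integer matrix (lines × pixels) plus `<file>.meta.json`
  with `line_time_s`, `pixel_size_um`, `origin_um`, `bead_band_pixels`;
- simulation truth and run reports: JSON.

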