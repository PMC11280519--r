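# afmonitor

Window-level detection of atrial fibrillation (AF) from inter-beat (RR)
interval series, built for the telemonitoring setting where a wearable
single-lead ECG device measures beats and transmits only the sequence of
intervals — a few hundred bytes every two minutes — to a service that
classifies the rhythm.

The package is aimed at researchers and engineers prototyping such
pipelines: it contains the detector itself, a software emulation of the
device front end, a seeded synthetic rhythm generator so everything runs
with no external data, I/O for the standard formats involved (WFDB
records and rhythm annotations, RR CSV, the 2-byte interval packet), and a
windowed evaluation harness.

## The algorithm

For each non-overlapping 2-minute window of RR intervals the detector
forms the successive differences δRR(i) = RR(i) − RR(i−1) and histograms
the pairs (δRR(i), δRR(i−1)) — the Lorenz (Poincaré) plot — on a 31×31
grid of 40 ms bins. The grid is partitioned into 13 regions; region 0 is
the square within 80 ms of the origin, where normal sinus variability
lives. With BinCountₙ the number of populated bins and PointCountₙ the
number of points in region n:

    IrregularityEvidence = Σ_{n=1..12} BinCountₙ
    PACEvidence = Σ_{n∈{1..4,5,6,10}} (PointCountₙ − BinCountₙ)
                − Σ_{n∈{7,8,12}} (PointCountₙ − BinCountₙ)
    AFEvidence  = IrregularityEvidence − OriginCount − 2·PACEvidence

where OriginCount is the number of points in region 0. A window is
classified **AF** when AFEvidence ≥ 50. The sparsity term is large when
the scatter is dispersed (AF), the origin term rewards concentrated
normal rhythm, and the PAC term discounts the repeated short-long
signature of premature atrial contractions with compensatory pauses so
they are not mistaken for fibrillation. Everything is exact integer
arithmetic.

## Worked example

```r
library(afmonitor)

# an AF-like window: uncorrelated RR, uniform 400-1200 ms, 2 minutes
af <- gen_af_rr(mean_rr_ms = 800, spread_ms = 400, duration_s = 120, seed = 1)
classify_window(af)
#> window: AF (AFEvidence 90, 148 intervals)
classify_window(af)$indices
#> af_indices: irregularity 121, PAC 13, origin 5 -> AFEvidence 90 (146 points)

# a normal-sinus window: AR(1) RR, mean 800 ms, SDNN 30 ms
nsr <- gen_nsr_rr(mean_rr_ms = 800, sdnn_ms = 30, duration_s = 120, seed = 1)
classify_window(nsr)
#> window: NSR (AFEvidence -146, 148 intervals)
```

The AF window populates 121 distinct off-origin bins with only 5 points
near the origin, driving AFEvidence (90) past the threshold of 50; the
sinus window puts essentially every point in the origin region, so its
AFEvidence is deeply negative.

The same thing end to end through the command-line interface (a thin
wrapper installed as `exec/afmonitor`; `Rscript exec/afmonitor …` from a
checkout):

```
$ afmonitor simulate --segments NSR:600,AF:600 --seed 42 --out demo
$ afmonitor detect demo.rr.csv --out demo.windows.csv
demo.rr: 10 windows, 5 AF, 0 undetermined
$ afmonitor evaluate . 
Patient     Accuracy Sensitivity Specificity
demo           1.000       1.000       1.000
pooled         1.000       1.000       1.000
```

The per-window CSV holds one row per 2-minute window
(`record,window_start_s,n_rr,irregularity,pac,origin,af_evidence,verdict`);
undefined metrics (zero denominators) print as `//` in reports. The
`stream` subcommand replays a record through the packet codec
(encode → decode → classify, one event per 2-minute packet with its
payload size in bytes), and `mask validate` checks a custom 13-region
segmentation file against the detector's geometric invariants.

## Evaluating against the public AF database

The detector's headline figures on real data come from the MIT-BIH Atrial
Fibrillation Database (PhysioNet `afdb`, 23 ten-hour records; record
07859 is conventionally excluded, leaving 22 — `afdb_roster()`). That
data is not shipped here. If you download it, point `evaluate` at the
directory: WFDB records are read, beats detected with the Pan-Tompkins
front end, windows scored against the `.atr` rhythm annotations, and a
per-patient table with a pooled row is written. Reported numbers will
depend on the 13-region mask geometry (see the vignette); the built-in
mask is a documented reconstruction of the published drawing and can be
replaced with `--mask`.

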