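# mmglam

Analysis of magnetomyographic (MMG) recordings of pelvic floor muscle
contractions.

The levator ani muscles (LAM) support the pelvic organs and are stretched
far beyond normal skeletal-muscle limits during vaginal birth; injury to
them initiates many pelvic floor disorders. MMG recorded over the pelvis
with a 151-sensor SQUID array measures the magnetic fields of LAM
depolarisation non-invasively. This package implements the full analysis
chain for such recordings — voluntary Kegel contractions of graded
intensity, recorded in the third trimester of pregnancy and again
postpartum, with surface EMG and ECG side channels — together with a
protocol-faithful synthetic-session generator so that every stage is
testable without access to raw recordings (none are publicly deposited).

## The analysis

For each moderate-Kegel (MK) epoch, cut from −3 s to +10 s around the
contraction trigger and baseline-corrected against the pre-trigger 3 s,
the pipeline computes over the lower sensors (those closest to the
muscles):

- **SNR (dB)** = 10·log10( (RMS_signal / RMS_baseline)² ); epochs with
  SNR < 1 dB are discarded, and a subject with no surviving epochs in a
  session is excluded from the paired analysis;
- **RMS amplitude** (fT): sliding-window RMS (200 ms window, 199 ms
  overlap) smoothed by a 100-point moving average;
- **Total power**: Welch PSD (1 s Hann windows, 50% overlap), density
  summed over 20–200 Hz;
- **rPSD_L / rPSD_M / rPSD_H**: band power fractions over 20–80, 80–140
  and 140–200 Hz (normalised by total power, summing to 1).

Preprocessing before epoching: frequency-dependent subtraction (SUBTR) of
thigh interference using the array's edge sensors as references (per-STFT-bin
complex regression), 20–200 Hz 4th-order Butterworth band-pass plus 60 Hz
notch (both zero-phase), FastICA rejection of ECG-correlated and
edge-concentrated components, and ECG-referenced cardiac removal from the
EMG channels.

Parameters are grand-averaged per subject across kept MK epochs and each
parameter is compared between pregnancy and postpartum with a two-sided
paired Student t-test (alpha 0.05) preceded by a Shapiro–Wilk normality
check on the paired differences:

t = mean(d) / ( sd(d) / √n ),  d = x_3T − x_PPT,  df = n − 1.

## Worked example

Simulate a small paired study (reduced 30-sensor array for speed), run one
session through the full chain, and look at the per-epoch features:

```r
library(mmglam)

ch    <- makeSensorArray(30, 6, 4)           # 30 MMG sensors + EMG/ECG
study <- simulatePairedStudy(3, sessionSpec(nCycles = 2), effectSpec(),
                             channels = ch, seed = 42)

ses  <- study$sessions[["S01_third_trimester"]]
prep <- preprocessRecording(ses$recording)   # SUBTR -> filters -> ICA
eps  <- extractEpochs(prep$recording, ses$events, labels = "MK")
eps@epochs <- lapply(eps@epochs, baselineCorrect)
qc   <- qcFilter(eps)                        # 1 dB SNR gate
epochSetFeatures(qc$kept)
#>   subject         session label epoch rms_fT total_power rpsd_L rpsd_M rpsd_H snr_db
#> 1     S01 third_trimester    MK     1   25.5         777  0.418  0.361  0.221   7.05
#> 2     S01 third_trimester    MK     2   25.2         751  0.414  0.359  0.226   6.78
```

Both MK epochs clear the 1 dB gate comfortably (~7 dB); the recovered band
fractions sit near the generator's cohort profile (0.5 / 0.3 / 0.2,
per-subject jitter plus residual interference), and the ~25 fT RMS is the
80 fT burst amplitude averaged over the lower sensors' spatial falloff.

The same study end-to-end, through `runAll()`:

```r
cfg <- list(seed = 42, study = list(nSubjects = 3),
            array = list(nSensors = 30, nLower = 6, nEdgeRef = 4),
            session = list(nCycles = 2))
runAll(cfg, "out")
read.csv("out/stats.csv")
#>     parameter n_pairs mean_3t   sd_3t mean_ppt  sd_ppt      t        p significant
#> 1      rms_fT       3  26.588  1.1505   22.671  1.1186 106.49 8.82e-05        TRUE
#> 2 total_power       3 847.190 78.6857  608.243 60.2012  22.02 2.06e-03        TRUE
#> 3      rpsd_L       3   0.449  0.0366    0.385  0.0371 119.91 6.95e-05        TRUE
#> 4      rpsd_M       3   0.343  0.0310    0.402  0.0294 -58.60 2.91e-04        TRUE
#> 5      rpsd_H       3   0.207  0.0145    0.213  0.0151  -6.12 2.57e-02        TRUE
```

The injected postpartum effect is recovered with the expected directions:
RMS and total power decrease (positive mean difference, d = 3T − PPT),
the low-frequency band fraction decreases, and the middle band increases.
`out/` also holds the per-epoch feature table, the QC report (per-epoch
SNR, kept flags, excluded subjects), the generator's ground-truth
parameters, and a run manifest with seed, config hash and stage counts.

A thin CLI over the same functions lives at `inst/cli/mmgpipe.R`
(subcommands `simulate`, `preprocess`, `epoch`, `features`, `stats`,
`run-all`).

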