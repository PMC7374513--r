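# pentrack

Long-term tracking and individual identification of a fixed number of
group-housed animals (pigs, in the motivating deployments) from per-frame
keypoint detections. The package is aimed at researchers in precision
livestock farming and behavioural science who have a top-down camera over a
pen, a per-frame detector that emits shoulder/tail keypoints and ear
positions, and an ear-tag classifier — and who need continuous, identified
trajectories over videos hundreds of thousands of frames long.

Neural-network inference is out of scope: `pentrack` starts from detector
output (a JSON-lines file of per-frame detections) and includes a synthetic
pen simulator, so the whole pipeline runs and is tested without any video
data.

## Method

The pen houses a known, constant number of animals N. Each detected
instance is a shoulder–tail pair x = {s, t} of image coordinates. Three
stages turn raw detections into identified tracks:

**1. Fixed-cardinality track interpolation.** Frames with more than N
instances are reduced by removing the highest-cost detections, with cost

    C(x) = ( |(t→s) − s| + |(s→t) − t| ) / ( 2 |s − t| (score_s + score_t) ),

the normalised back-and-forth error of the detector's part-association
estimates, scaled by the part scores (each in [0.25, 1]). A forward scan
then associates consecutive frames by the Hungarian algorithm and copies
any unmatched previous-frame entry into the current frame; a backward scan
mirrors the rule. The result is exactly N linked chains spanning all T
frames; every copied ("duplicate") position is replaced by time-weighted
linear interpolation between its nearest flanking real detections.

**2. Ear-tag marker evidence.** A visible ear carries a classifier
probability vector over the N identities. Ears are linked *softly* to
instances: the normalised back-and-forth ear–shoulder distance d maps to a
link probability max(1e−6, e^(−10 d)), and an instance's identity
likelihood is the product over all ears of

    p(link) · p(tag → n) + (1 − p(link)) / N ,

normalised over n. Unlinked ears wash out; a confidently linked,
confidently classified ear drives the vector toward one-hot.

**3. Identity smoothing and assignment.** For each identity, occupancy
over the N track slots is a hidden Markov chain. The transition weight
between poses is an exponential-mixture "stay put" density of the pose
displacement δ = √(|Δs|² + |Δt|²),

    p(δ) = 0.6·(9/10)e^(−9δ/10) + 0.3·(1/6)e^(−δ/6) + 0.1·(1/30)e^(−δ/30),

normalised per source slot (see the methods vignette for why), and the
marker likelihoods are the emissions. Posterior marginals are computed
with the log-sum-exp-stabilised forward–backward algorithm — long videos
underflow any naive implementation — and each frame's slot-to-identity map
is the Hungarian assignment minimising summed negative log posteriors.
Three scenarios are supported: `location` (tracks only), `initialized`
(first-frame identities annotated) and `uninitialized` (identities must be
inferred from intermittent tag sightings alone). Evaluation uses
mutual-nearest matching gated by the ground-truth body length; with fixed
cardinality, precision always equals recall.

## Worked example

Simulate a moderately hard pen (8 animals, 600 frames at 5 fps, day-time
tag visibility), track it blind, and score it:

```r
library(pentrack)
cfg <- scenario_presets("day_medium", N = 8, T = 600, seed = 11)
sim <- simulate_pen(cfg)
res <- track_identities(sim$frames, N = 8, scenario = "uninitialized",
                        m = cfg$step_model)
res
#> pentrack result (uninitialized scenario): 8 animals x 600 frames
#> track_set: 8 tracks x 600 frames; 207 interpolated entries (4.31%)
#> identity relabelling events between adjacent frames: 24
precision_recall(sim$gt, res, mode = "location_id")
#> Tracking evaluation (location_id matching, uninitialized scenario)
#>   targets: 8  frames: 600
#>   TP: 4693  FP = FN: 107
#>   precision = recall = 0.9777
```

4.31% of track entries were fabricated by duplication and interpolation
(the simulator dropped ~5% of detections), and 97.8% of the 4800
frame-animal poses are matched with the correct identity despite no
first-frame annotation. Refitting the displacement mixture to the observed
trajectories recovers components on the three characteristic time scales:

```r
fit_motion_model(displacements_from_tracks(sim$gt), k = 3, seed = 11)
#> Exponential-mixture fit (EM), 3 components, n = 4792
#>   weight    rate   mean
#>  0.60886 0.91137  1.097
#>  0.31599 0.13983  7.152
#>  0.07515 0.02182 45.820
#> log-likelihood: -11252.821 (converged, 169 iterations)
```

The same pipeline is available from a shell via the bundled CLI
(`system.file("cli", "pentrack", package = "pentrack")`):

```sh
pentrack simulate --preset day_medium --n 8 --frames 600 --seed 11 --out d/
pentrack track --detections d/detections.jsonl --n 8 \
         --scenario uninitialized --out d/
pentrack evaluate d/gt.csv d/tracks.csv --mode location_id
```

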