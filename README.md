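# blsentropy

Feature extraction for **binary time series** built on branch length
similarity (BLS) entropy. Binary series are everywhere once data are
thresholded — geyser eruptions, recession indicators, pollution
exceedances, discretized animal movement — yet most time-series toolkits
are built for continuous signals. This package characterizes the
*distribution of the "1" signals* directly, for anyone who needs to locate
density regimes and regime changes in a 0/1 sequence or to compare two
such sequences in a distribution-aware way.

## The method

The "1" signals of a series of length `L` are mapped onto a **time
circle** of circumference `L`, each at its own time. Each signal defines a
star network whose branch lengths are its circular time distances
`d(t_i, t_j) = min(|t_i − t_j|, L − |t_i − t_j|)` to every other signal.
With branch probabilities

```
p_j = L_j / Σ_k L_k
```

the BLS entropy of the focal signal is the normalized Shannon entropy

```
S = − Σ_j p_j log p_j / log n,      S ∈ [0, 1],
```

equal to 1 when all branches are equal, near 0 when one branch dominates.
Evaluating `S` at every signal in time order yields the **entropy profile**
`S(t̃)`, whose geometry carries the series' structure:

* **local maxima / minima** — times where the rate of change of signal
  density is zero (high entropy ↔ locally sparse, low ↔ locally dense);
* **slope** — the degree of local density change;
* **inflection points τ** — times where the density regime changes;
* **ρ similarity** — `max_k corr(S₁, shift_k(S₂))`, the maximal Pearson
  correlation over cyclic shifts of one profile against another, a
  distribution-aware alternative to the Euclidean distance between raw
  0/1 vectors.

A trajectory front-end converts planar movement tracks into binary series
(eight 45° turning-angle categories → 3-bit codes), and seeded generators
(uniform, concatenated, triangular-gap, fractal-landscape, random,
correlated random walk) reproduce every synthetic input used in the tests.

## Worked example

A series whose density halves at `t = 500`: a spacing-2 uniform part
followed by a spacing-5 part, each 500 steps.

```r
library(blsentropy)

q12 <- concat_series(uniform_series(500, 2), uniform_series(500, 5))
p12 <- entropy_profile(q12)
p12
#> BLS entropy profile: 350 signals, source L = 1000
#>   S in [0.958591, 0.979760]

inflection_points(p12)
#>   time     strength kind index_left index_right
#> 1  500 0.0002700101 fall        250         251

local_extrema(p12)$minima
#>   index time     value prominence
#> 1   126  251 0.9585907 0.02116931

local_extrema(p12)$maxima
#>   index time     value prominence
#> 1   301  751 0.9797601 0.02116931
```

The single inflection lands exactly on the junction `t = 500` (`"fall"`:
density decreases there). The profile minimum sits at `t = 251`, the
centre of the dense half, and the maximum at `t = 751`, the centre of the
sparse half — locally dense stretches carry low entropy, sparse stretches
high.

Comparing two fractal-landscape series that share their random structure
and differ only in smoothness `H`:

```r
a <- landscape_series(0.2, grid_shape = c(50, 50), seed = 3, phase_seed = 3)
b <- landscape_series(0.3, grid_shape = c(50, 50), seed = 3, phase_seed = 3)
profile_rho(entropy_profile(a), entropy_profile(b), resample_to = 256)$rho
#> [1] 0.9967731
```

The same operations are scriptable from a shell via the bundled launcher
(`inst/cli/bls`), with subcommands `profile`, `features`, `rho`,
`simulate` and `traj2bin`; every run logs its parameters to stderr and
writes tab-separated results to stdout or `--out`.

```sh
Rscript inst/cli/bls simulate uniform --length 500 --spacing 2 --out q1.txt
Rscript inst/cli/bls profile --in q1.txt --out q1.profile.tsv
Rscript inst/cli/bls features --in q1.profile.tsv --threshold 0.01
```

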