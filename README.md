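# anodet

Privacy-preserving anomaly detection for cohorts monitored by wearable
sensors.

A school or campus health programme collects, for each of *N* students, *M*
health criteria (heart rate, blood pressure, ...) sampled at *K* time
points — an `N × M × K` tensor of sensitive readings. Shipping those raw
curves to a cloud platform for analysis is both slow and a privacy risk.
`anodet` implements an index-based alternative: each health curve
`A_ij = (a_ij1, ..., a_ijK)` is reduced on-device to a single sign bit of a
random-hyperplane projection,

    Ω_ij = A_ij · B,   B ~ Uniform[−1, 1]^K,   Ψ_ij = 1{Ω_ij > 0},

and a student's *M* bits are packed (MSB first) into one *M*-bit integer
index `π_i`. This is the classical random-hyperplane LSH family: two curves
at angle θ agree on a bit with probability `1 − θ/π`, so near-identical
students collide and dissimilar ones do not, while the index itself reveals
no raw reading. The construction is repeated `q` times in each of `p`
independent hash tables; pairwise similarity is the match count

    Sim(s_i, s_j) = Σ_{z=1..q} 1{ ∃ t ≤ p : π_iz^(t) = π_jz^(t) },

an integer in `0..q`. Students with `Sim ≥ T` are deemed similar, similarity
groups are the connected components of that graph, and **students with no
similar peer — degree-zero vertices — are flagged as anomalies**.

The package ships the full pipeline (tensor containers and CSV/JSON I/O,
seeded index construction, similarity and threshold graphs, clustering and
anomaly reporting), a synthetic cohort generator with latent health groups
and planted anomalies, an evaluation harness that scores held-out-entry
prediction by MAE/RMSE against a user-based collaborative-filtering
baseline, and a small command-line interface.

## Worked example

```r
library(anodet)

cohort <- generate_cohort(generator_config(N = 100, M = 20, K = 64,
                                           n_groups = 4,
                                           anomaly_fraction = 0.05,
                                           seed = 42))
fit <- ano_det(cohort, p = 6, q = 6, T = 2, seed = 42)
summary(fit)
```

```
Run config: p=6 tables, q=6 repetitions, T=2, seed=42
Students: 100; groups: 14 (sizes 1, 22, 23, 22, 1, 1, 23, 1, 1, 1, 1, 1, 1, 1); anomalies: 10
Pairwise match-count distribution (Sim = 0..q):

   0    1    2    3    4    5    6
4242  428  216   53   11    0    0
Neighbor counts: min 0, median 5.0, max 16
Against planted truth: recall 1.00, precision 0.50
```

The cohort has 5 planted anomalous students among 100; at `p = q = 6`,
`T = 2` the detector recovers all five (recall 1.00) and additionally flags
five borderline normal students (precision 0.50) — students whose noisy
curves happened to collide with nobody. The four 22–23-member groups are the
latent healthy profiles. `plot(fit)` draws the similarity graph with
anomalies as red squares; `predict(fit, heldout)` imputes hidden readings
from threshold neighbors.

The same pipeline is scriptable step by step (`build_index`,
`similarity_matrix`, `threshold_graph`, `detect_anomalies`) or from a shell
via the CLI wrapper:

```sh
Rscript inst/cli/anodet.R simulate --config gen.json --output cohort.csv --labels labels.json
Rscript inst/cli/anodet.R index    --input cohort.csv --config run.json --output index.json
Rscript inst/cli/anodet.R detect   --index index.json --threshold 2 --output report.json
```

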