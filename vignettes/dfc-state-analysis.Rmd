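---
title: "Dynamic connectivity states and graph indicators: methods and design"
author: "dfcstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states and graph indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

## The analysis in one paragraph

Resting-state fMRI coupling between brain regions is not constant: the
correlation structure of parcellated ROI signals drifts between recurring
configurations ("states"). This package implements the standard
sliding-window route to those states and the comparisons built on top of
it, as used to study how intracranial electrical stimulation changes brain
networks in refractory epilepsy: per-window Pearson correlation matrices
(`slidingWindows`), pooled K-means clustering of the vectorized windows
into states (`kmeansStates`), cluster-quality criteria for choosing window
length, step and state count (`qualityCriteria`, `sweepClustering`),
state metrics — strength, occupancy rate, dwell time, transitions per
minute (`stateMetrics`) — lobe-level centroid summaries (`lobeSummary`),
binarized-network graph indicators in static and per-window dynamic form
(`binarizeFC`, `graphIndicators`, `dynamicIndicators`), and nonparametric
pre/post group comparison with ADF/KPSS stationarity and FFT periodicity
analysis of dynamic indicator traces (`mannWhitney`, `groupCompare`,
`stationarityTest`, `periodicityTest`). A synthetic-cohort generator
(`simulateCohort`) plants Markov-switching connectivity states with known
ground truth so that every stage can be tested without any imaging data.

## Windowed connectivity

A run is a T x N matrix of parcellated signals with repetition time TR
(seconds). Windows are rectangular (boxcar), specified by a length in
seconds — converted to whole TRs by rounding to nearest, ties upward — and
a step in TRs; coordinates are 0-based and half-open, and a run of length T
yields `floor((T - L)/s) + 1` windows. Within each window the N x N Pearson
matrix is computed as-is: no Fisher z-transform, no taper, no within-window
detrending, because every extra transform would move the cluster centroids
that downstream metrics are defined on. Correlations are never computed
across run boundaries; a zero-variance ROI raises an error naming the ROI
and window rather than propagating NaNs. Defaults are 60 s windows, 1 TR
step: the quality criteria below are flat-to-optimal around 40-80 s, and a
1 TR step retains the most temporal detail.

## State identification

All windows of all participants and both sessions are vectorized (upper
triangle, length N(N-1)/2) and clustered together by Euclidean K-means, so
pre- and post-stimulation sessions share one set of centroids and can be
compared on occupancy of the *same* states. Initial centroids are drawn
uniformly from the data points (not kmeans++), Lloyd iterations run until
the assignment is unchanged (cap 300), ties in nearest-centroid assignment
break toward the lower state index, an emptied cluster is reseeded with the
point farthest from its centroid, and the best of 10 restarts by
within-cluster sum of squares is kept — all deterministic given the seed,
which is recorded on the model. States are relabelled by descending
centroid strength (mean upper-triangle r), so state 1 is always the
strongly connected state.

Four quality criteria guide parameter choice: the inertia elbow, the mean
silhouette coefficient (Euclidean dissimilarity; a sample in a singleton
cluster contributes 0), the Calinski-Harabasz ratio of between- to
within-cluster dispersion, and the Davies-Bouldin index with a cluster's
scatter defined as the average member-to-centroid distance. These are
implemented directly from their defining formulas and are verified against
independent brute-force evaluations to 1e-10 in the test suite; on small
problems (up to 4096 samples) all distances are computed by exact
differencing, while larger pools use a chunked BLAS expansion whose ~1e-8
relative error is negligible at that scale.

## State metrics

Per participant and session: occupancy rate is the fraction of windows
assigned to a state; dwell time is the mean duration of uninterrupted
consecutive-window visits (window runs never cross acquisition runs;
run-length x step x TR seconds), reported as missing — not zero — for a
state the participant-session never enters, and excluded from group means;
the transition rate is label changes per minute of windowed time. Strength
appears twice: `strength` is the mean upper-triangle r of the state
centroid (a property of the shared state, identical pre and post by
construction), and `strength_windows` is the mean upper-triangle r of the
member windows of that participant-session. The second is what a pre/post
strength comparison has to use: with pooled clustering the centroid cannot
differ between sessions, but the windows assigned to a state genuinely
weaken after stimulation, and `strength_windows` resolves that. Occupancies
sum to one per participant-session by construction.

## Graph indicators

Connectivity matrices are binarized either by proportional density (top
`floor(d * N(N-1)/2)` upper-triangle edges by r, ties at the cutoff broken
lexicographically so the count is exact; negative correlations excluded by
default) or by an absolute threshold (r strictly greater than the cutoff).
Density thresholding keeps edge count comparable between sessions when the
overall correlation level drops — which is exactly the planted effect — so
the pre/post indicator comparison uses the absolute rule (default 0.1),
where a global weakening is allowed to show up as a sparser graph.

The six indicators are: mean nodal clustering coefficient (triangle
definition, degree < 2 contributing 0), maximum k-core number, modularity
Q of a greedy agglomerative modularity-maximizing partition, degree
assortativity (missing when undefined, e.g. regular graphs), global
efficiency (mean inverse shortest-path length, unreachable pairs
contributing 0), and local efficiency (mean over nodes of the global
efficiency of the node's open-neighborhood induced subgraph — paths do not
leave the neighborhood). Computations run on igraph, except local
efficiency, which is assembled per node from induced subgraphs because
igraph's built-in allows paths through the rest of the graph. All six are
verified against brute-force implementations on every connected graph with
up to 6 nodes in the test suite. The dynamic variant applies the same
binarization and indicators to every window of a run in order, giving one
indicator trace per run — a multilayer (one layer per window) view.

## Statistics

Group comparison is the two-sided Mann-Whitney U test across participants,
preceded by Shapiro-Wilk normality and Brown-Forsythe Levene checks that
document why the parametric route is not taken. For small samples
(n1 + n2 <= 12) the p-value is exact by complete enumeration of rank
arrangements; larger samples use the normal approximation with tie and
continuity correction (the two branches agree within 0.02 at n = 6 + 6 on
untied data). The reported statistic is the standardized U of the pre
group, so a positive statistic reads as "decreased after stimulation";
direction is called only when p < alpha (default 0.05, uncorrected, with
optional Benjamini-Hochberg). The design is formally paired, but the
unpaired Mann-Whitney is the primary route for fidelity to field practice;
a paired Wilcoxon option exists. Per-participant tallies rerun the same
test on window-level dynamic indicator values within each participant and
count who increased, decreased, or did not change; participants with fewer
than two windows in a session are reported as untested rather than
silently dropped.

Stationarity of a dynamic indicator trace combines an ADF unit-root test
(constant-only regression, augmentation lag chosen by AIC on a common
estimation sample, p by interpolation in the Dickey-Fuller tau table,
clamped to [0.01, 0.99]) with a KPSS level-stationarity test (Bartlett
long-run variance, truncation lag `trunc(4 (n/100)^0.25)`, p clamped to
[0.01, 0.10]): ADF rejecting while KPSS does not gives "stationary", the
reverse "nonstationary", anything else "conflicting"; a constant trace is
stationary with a degenerate flag. Periodicity linearly detrends the trace,
takes the FFT, and reports the dominant nonzero frequency (cycles/window),
its period in seconds via the window stride, and the peak-to-median power
ratio (the Nyquist bin is excluded for even-length traces: it carries no
phase information and its chi-squared(1) null inflates the maximum);
"no meaningful periodicity" is operationalized as a ratio below 10.
That cutoff is calibrated for traces of roughly 60-270 windows — the run
lengths this pipeline produces — where the expected maximum of the null
power spectrum sits well below 10 times the median; much longer traces
would need a larger cutoff (the extreme-value growth of the spectral
maximum is logarithmic in the trace length).

## The synthetic cohort

`simulateCohort` generates what the pipeline assumes: per-TR hidden state
labels from a first-order Markov chain, and observations drawn i.i.d. from
a zero-mean multivariate normal with the active state's covariance (an
optional AR(1) coefficient is available but off by default — the pipeline
consumes windowed correlations, for which the state-conditional covariance
is the structure that matters). Ground truth records the label sequence,
the analytic stationary occupancy (left unit eigenvector) and the analytic
mean sojourn `1/(1 - p_kk)` TR; window-level truth is defined by majority
of per-TR labels with ties to the earlier state, which is what recovery
tests score against.

The `paper_like` scenario plants the studied contrast at desk scale: 30
ROIs in 6 equal lobes (the shipped AAL-116 six-lobe map serves real-sized
data; 30 keeps the pooled clustering and sweeps fast), TR 2 s, per
participant two ~4.8-minute pre-op runs and two 10-minute post-op runs. The
strong state has within/between-lobe correlations 0.70/0.13 (mean
upper-triangle r about 0.21) and the sparse state 0.10/0.075 (about 0.079);
pre-op switching gives the strong state stationary occupancy 0.58 (mean
sojourns 150 and 108.62 TR), post-op 0.16 (sojourns 30 and 157.5 TR), and
all post-op correlations are scaled by 0.85. Three design constraints fixed
these numbers: the two mean strengths and the two occupancies mirror the
magnitudes reported for real stimulation data; the within/between contrast
and sojourn lengths are large enough that the planted window-level
structure is actually recoverable by the pooled clustering (states whose
visits are shorter than the window cannot be labelled by majority rule at
better than chance near transitions — a generator that plants unrecoverable
structure tests nothing); and the post-op covariance scale stays close
enough to 1 that post-strong windows remain nearest the strong centroid
(at much stronger scaling the post-strong distribution migrates toward the
sparse centroid and the shared two-state geometry collapses). Planted dwell
times consequently do not mirror the real-data dwell magnitudes — those
would put sojourns at or below the window length — only their direction of
change. The `null_no_effect` scenario is a single state with identical
settings pre and post, used for type-I-error calibration.

What passing recovery tests on this generator shows — and what it does
not: the pipeline recovers planted covariance-switching structure,
directions of planted effects, and its statistical calibration holds under
the null. Real fMRI adds hemodynamic autocorrelation, motion and scanner
artifacts, non-Gaussian tails and spatially structured noise, none of
which the generator emulates; results on real data depend additionally on
preprocessing choices outside this package's scope.

## Numerical and design choices worth knowing

* Problem sizes in the shipped tests: the recovery cohort is 20
  participants (15,440 pooled windows of 435 features), the chain-recovery
  experiment uses 16 runs of 5,000 TR per condition at 12-TR windows
  (single-run occupancy of a slowly switching chain has sampling noise of
  several percentage points, so recovery is asserted on the pooled runs),
  and calibration loops use 100 replicates; these sizes make the full
  suite run in tens of minutes on one core while leaving the measured
  margins comfortable. The chain-recovery conditions keep the studied
  occupancies (0.58/0.16) but use sojourns of at least five windows,
  because window-majority dwell is only a consistent estimator of sojourns
  that clearly exceed the window length.
* K-means determinism: data-point initialization, lowest-index tie-breaks,
  farthest-point reseeding of emptied clusters, per-iteration inertia trace
  exposed for the monotonicity test.
* The silhouette of a singleton-cluster sample is 0; an all-singleton
  clustering is an error, as is computing criteria for k = 1.
* Mann-Whitney with all values tied across both groups returns p = 1 and
  "no_change" rather than an error.
* ADF/KPSS p-values are table lookups with clamping, as in the classical
  implementations; a `clamped` flag is set when the statistic falls outside
  the table.
* Manifest TRs are required, never inferred from data; all seconds-valued
  metrics inherit them.
* The AAL-116 lobe map ships as an editable data file because the
  anatomical grouping is a convention, not a computation; any ROI set can
  be supplied through `loadLobeMap`.

## Known limitations

Sliding-window correlation is itself a smoother: states whose sojourns are
shorter than about twice the window length are systematically blurred, and
window-level dwell times are biased upward by majority-rule widening and
downward by run-boundary censoring — the recovery tests bound this at the
scales they test (within 15% of the analytic sojourns there), but dwell
times near the window length should be read qualitatively. The group test
treats a paired design as unpaired, following field practice; the paired
option is provided. Greedy modularity is a lower bound on optimal Q.
P-values are uncorrected by default, matching the practice the pipeline
reproduces, with BH correction available.
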