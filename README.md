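# dynGRN

Heuristic inference of dynamical gene-regulatory networks (GRNs) from
time-resolved gene-expression data measured under multiple stimuli in
multiple experiments.

Time-course experiments in systems biology — say, stem cells stimulated with
two different growth factors in separate experiments — produce a handful of
expression values per gene on a short, unevenly spaced time grid. dynGRN
infers from such data a sparse system of coupled ordinary differential
equations,

    dx/dt = A x + B u,

where `x` holds one state per gene, `u` the stimuli as 0/1 step inputs, `A`
the gene–gene interaction coefficients (negative diagonal: self-regulation
and mRNA degradation) and `B` the stimulus effects. Instead of estimating
all `N² + M·N` coefficients at once, a greedy heuristic builds the model one
*sub-model* (one gene's equation) at a time: basic structures
(self-regulation + one input) are fitted for every remaining gene, the
best-reproduced series is included and refined by **growing** further
incoming connections, **raising** the dynamic order (integrator chains give
S-shaped responses without extra parameters) and **pruning** superfluous
connections. Parameters are initialised by weighted linear regression on
numerically differentiated series and refined by bounded L-BFGS-B least
squares; connections from genes not yet in the model are fitted against
their data and become global feedbacks. Prior knowledge enters either as
hard ("fix") structural constraints or as a score-weighted ("flexible")
penalty `λ · Σ s·d` on sign disagreements in the objective.

The package ships the full benchmark apparatus for this class of methods:
generators for cross-talk benchmark systems (full / limited / no cross-talk),
noisy data simulation on an exponentially spaced six-point grid,
edge-confusion evaluation (sensitivity, specificity, precision, F-measure
with the sign-aware false-positive split), `allowedError` sweeps, and
resampling-based edge-frequency validation, plus DOT graph and time-course
export and a small command line front end (`inst/scripts/dyngrn.R`).

## Worked example

Generate a 4-gene, 2-stimulus limited-cross-talk benchmark, simulate two
single-stimulus experiments (six time points, Gaussian noise, sd 0.05),
infer the network and compare it with the ground truth:

```r
library(dynGRN)

bm  <- generateBenchmark("LCT", seed = 7)
ds  <- generateData(bm, scenario = "M", noiseSd = 0.05, seed = 7)
fit <- inferNetwork(ds)
fit
#> GRNInference
#> GRNModel: 4 genes, 2 stimuli, 4 states; 7 gene-gene and 6 input edges
#>   inclusion order: G2 -> G1 -> G3 -> G4
#>   sub-model errors: G1=0.01157  G2=0.009099  G3=0.003957  G4=0.005504
#>   coupled simulation error: 0.03435

evaluateStructure(fit, bm)
#> GRNEvaluation
#>   counts:   TP=9  TN=7  FPn=8  FPs=0  FN=0
#>   measures: SE=1.000  SP=0.467  PR=0.529  FM=0.692
```

The inclusion order follows the hierarchy from the stimuli: the two directly
driven genes enter first, the downstream convergence gene later. The
sub-model errors are the weighted squared deviations per time series
(measured points weight 1, spline-interpolated points 0.25); the coupled
error re-simulates the complete system. Against the generating truth, all
nine true connections are recovered with correct signs (sensitivity 1);
at the default `allowedError` of 0.005 the fit also keeps eight spurious
small connections (specificity 0.47) — sweep `allowedError` with
`sweepAllowedError()` and compare models to trade error against sparsity,
and use `resampleValidate()` to rank connections by their recurrence under
data perturbation. `exportDOT()` writes the graph for Graphviz;
`exportTimecourses()` tabulates measured, interpolated and simulated
series.

The methods vignette (`vignettes/network-inference.Rmd`) documents the
model, the heuristic's rules and thresholds, the benchmark design and the
known limitations.

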