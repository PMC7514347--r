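# critmem

Criticality-mediated memory consolidation in attractor neuronal networks —
simulation, estimation and spike-train analysis in R.

## The scientific problem

How can a weak, sparse input compete with memories a network already stores,
and end up consolidated as a new distributed memory? `critmem` implements the
two complementary analyses behind that question:

1. **An in-silico half.** A Hopfield-type network of `N` binary neurons
   (`S_i = ±1`) on a directed small-world graph with fixed in-degree `k`.
   Neurons feel the field `h_i = (1/k) Σ_{j→i} J_ij S_j` and update by a
   heat-bath rule: align with `sign(h_i)` with probability
   `P = 1/(1 + e^{−2|h_i|/T})`. Native memories `ξ^μ` enter through
   outer-product couplings `J_ij = (1/p) Σ_μ ξ_i^μ ξ_j^μ`; a new
   configuration `ξ^e` impinges either through a small clamped subset `N′`
   with strengthened outgoing couplings `(w_e/p) ξ^e_i ξ^e_j`, or as a
   global field `(w_ext/p) ξ^e_i`. Learning is the unbounded Hebbian rule
   `ΔJ_ij = ε S_i S_j`. The package measures overlap and stability order
   parameters, estimates the critical temperature `T_c` (half-maximum
   interpolation or sigmoid fits of flip curves), the shift `ΔT_c(ε)`
   induced by consolidation, the input-robustness and global-field phase
   maps, consolidation times, and the classic `T = 0` storage capacity
   `α_max = p_max/N ≈ 0.14`.

2. **A spike-train half.** Pooled spiking activity per slow-wave-sleep bout
   is binned into 16 ms intervals and its branching parameter `σ` (expected
   events triggered per event; `σ = 1` critical) is estimated by multistep
   regression: lag slopes `r_k = Cov(a_t, a_{t+k})/Var(a_t)` fitted with
   `r_k = b σ^k + c`, which is invariant to subsampling of the event
   stream. Non-stationary bouts (drift, up/down switching, runaway) are
   screened out; per-subject epoch means and per-group changes `Δσ` are
   reported alongside a behavioural learning score. A synthetic-cohort
   generator produces every input file the pipeline reads, with known
   ground truth.

## Worked example

Critical temperature of a single-memory network, then branching-parameter
recovery from a subsampled synthetic spike series:

```r
library(critmem)

top <- build_small_world(1000, 20, 0.1, seed = 1)   # directed small world
pat <- make_patterns(1000, 1, 0, seed = 2)          # one native memory
net <- embed_native(top, pat)
net
#> Coupled attractor network
#>   N = 1000, k = 20, p = 1 memories, 20000 weighted edges

sw <- protocol_prelearn_sweep(seq(0.4, 1.6, 0.2), 1000, 20, p = 1,
                              input_size = 0, realizations = 5, seed = 3)
sm <- summarize_sweep(sw)
round(sm[, c("temperature", "m_native", "m_native_sem", "flip")], 3)
#>   temperature m_native m_native_sem  flip
#> 1         0.4    0.687        0.131 0.036
#> 2         0.6    0.832        0.069 0.107
#> 3         0.8    0.500        0.104 0.323
#> 4         1.0    0.082        0.017 0.470
#> 5         1.2    0.042        0.006 0.489
#> 6         1.4    0.039        0.003 0.496
#> 7         1.6    0.031        0.003 0.498

tc_from_halfmax(sm$temperature, sm$m_native)
#> Transition fit (interpolation): T_c = 0.8404, slope = -2.09
```

The native overlap `m` is high in the ordered (sub-critical) regime, where
almost no neuron flips per iteration, and collapses at the transition, where
the flip fraction approaches its disordered asymptote 1/2; the half-maximum
crossing puts `T_c` near 0.84 at this desk scale (`N = 1000`; the mean-field
value is 1).

```r
ser <- simulate_branching(0.95, 0.5, 5e4, subsample_prob = 0.1, seed = 4)
mr_estimate(ser)
#> Branching estimate: sigma = 0.9483 (R2 = 1.000, 50000 bins)
```

Only 10% of the events of a `σ = 0.95` process are observed, yet the
multistep fit recovers `σ` to within 0.002 — the naive lag-1 slope would
read ≈ 0.3.

A full synthetic conditioning study (5 CFC + 3 sham subjects, two epochs of
sleep bouts each) runs end to end with:

```r
make_cohort("cohort_dir", seed = 11)
res <- analyze_cohort("cohort_dir")
res$groups   # per-condition mean change in sigma, sem, one-sample test
```

A thin command-line wrapper for the spike-train stages is installed at
`inst/scripts/critmem` (`synth-cohort`, `branching` subcommands); the model
protocols are R functions, documented in the methods vignette
(`vignettes/critmem-methods.Rmd`).

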