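# photokin

Parallel photocycle kinetic analysis of channelrhodopsin time-resolved
spectra and photocurrents.

Light-gated ion channels such as the anion channelrhodopsin *Gt*ACR1
traverse a photocycle after flash excitation. Time-resolved absorbance
data reveal the spectral intermediates; photocurrents reveal when the
channel is open. The two disagree unless the photocycle is modelled as
**parallel cycles**: a conductive cycle carrying the open-channel states
and one or more nonconductive cycles, running independently and summing
in the measured signal.

`photokin` implements the full analysis chain for this picture:

* **Spectral model** — skewed-Gaussian (Fraser–Suzuki) spectral forms on
  the wavenumber scale; basis matrices with conditioning checks
  (`make_spectral_form()`, `build_basis()`, `default_basis()`).
* **Kinetics core** — first-order schemes, rate-matrix assembly and
  eigen-decomposition with degeneracy grouping, time evolution,
  amplitude b-spectra, branch-rate law
  (`kinetic_scheme()`, `eigen_solve()`, `compute_b_spectra()`,
  `branch_rates()`).
* **Synthetic data** — a wild-type-like two-cycle ground-truth generator
  with seeded Gaussian noise and CSV/JSON serialization
  (`wt_like_model()`, `simulate_absorbance()`, `simulate_current()`).
* **Decomposition** — SVD rank estimation, global multi-exponential
  fitting by variable projection, sequential intermediate spectra,
  non-negative deconvolution into composition matrices
  (`svd_rank()`, `global_exp_fit()`, `sequential_from_b()`,
  `deconvolve_composition()`).
* **Cycle partitioning** — anchor-based partition of the composition
  into conductive/nonconductive cycles with explicit shared states and
  full enumeration of the feasible shared-state allocations
  (`partition_two_cycle()`, `split_three_cycle()`,
  `enumerate_shared_allocations()`, `partition_s97e_lowpH()`).
* **Scheme fitting** — rate templates with constraints and fixed slots,
  microscopic-rate fitting against apparent rates and b-spectra,
  identifiability diagnostics, equilibrium-vs-branching comparison
  (`scheme_topology()`, `fit_scheme_rates()`, `topology_catalog()`,
  `classify_equilibrium_vs_branching()`).
* **Current analysis** — exponential decomposition of current traces,
  component modification factors, alignment with conductive populations
  (`decompose_current()`, `modify_current()`, `align_current()`,
  `required_fast_modification()`).
* **Pipeline** — deterministic end-to-end runs and multi-seed parameter
  recovery experiments (`run_config()`, `run_pipeline()`,
  `recovery_experiment()`).

## The model in brief

State populations of a first-order scheme obey

```
dc/dt = A c,   c(t) = sum_k W[, k] exp(lambda_k t)
```

with the rate matrix `A` (columns sum to zero) and eigenvalues
`lambda_k` the observable apparent rates. The data matrix factorizes as

```
D(lambda, t) = E C_f(t)' = sum_j b_j(lambda) exp(-t / tau_j) + b_inf(lambda)
```

where `E` holds the spectral forms and the b-spectra `b_j = E (F W)_j`
combine eigenvector weights within each degeneracy group. Two facts
drive the parallel-cycle analysis: transitions between isospectral
states are spectrally silent (the channel-opening K -> O step is read
from the current rise, not the spectra), and cycles sharing a rate are
spectrally inseparable (degenerate eigenvalues, one combined amplitude
spectrum).

## Worked example

Simulate the wild-type-like two-cycle ground truth at 0.5% noise and run
the full analysis:

```r
library(photokin)

cfg <- run_config(seed = 11, noise = 0.005)
res <- run_pipeline(cfg)

res$kinetics
#> <apparent_kinetics> 5 exponentials + constant, RMS residual 0.0049
#>   lifetimes (s): 2.462e-07, 5.879e-06, 0.0001148, 0.002006, 0.1001

res$composition
#> <composition_matrix>
#>        In1   In2   In3   In4   In5   In6
#> K-like   1 0.745 0.682 0.509 0.140 0.000
#> L-like   0 0.254 0.317 0.490 0.190 0.000
#> M        0 0.000 0.000 0.001 0.100 0.000
#> R        0 0.001 0.001 0.000 0.571 0.999

res$partition
#> <cycle_partition> conductive 0.51 / nonconductive 0.49
#> ... (per-cycle and shared-state tables follow)

res$three_cycle
#> <three_cycle_partition> O1 = 0.37 (Cycle1a), O2 = 0.14 (Cycle1b), conductive 0.51

res$cycle2_fit$success
#> [1] TRUE
round(res$recovered_rates, 2)
#>      k_kl1      k_l1k      k_kl2      k_l2k     k_l2n1    k_o1_o2     k_o1_r
#> 2006192.34 2003745.80  100733.57  100609.41   29812.45     136.93     361.68
#>    k_n1_n2     k_n1_m     k_n1_r     k_slow
#>     192.60     101.27     204.74       9.99
```

The recovered composition reproduces the generating fractions (conductive
0.51, slow open state 0.14, M content 0.10) to the third decimal, and the
microscopic rates of the nonconductive cycle's equilibration block come
back within a few percent at this noise level.

The published anchor fractions for the *Gt*ACR1 conditions are built in:

```r
split_three_cycle(partition_two_cycle(
  photokin:::composition_from_anchors(0.38, 0.09)))  # wild type, acidic pH
#> <three_cycle_partition> O1 = 0.29 (Cycle1a), O2 = 0.09 (Cycle1b), conductive 0.38
```

## Documentation

The methods vignette (`vignettes/photocycle-analysis.Rmd`) documents the
model, the assumptions, the generator's realism limits and every
numerical convention (degeneracy tolerances, the labeling convention for
isospectral states, the degenerate-by-default opening rate, CSV/JSON
serialization). All exported functions carry full roxygen documentation.
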