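---
title: "Transient amplification in linear recurrent networks: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient amplification in linear recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transamp)
```

## The model

`transamp` analyses networks of $N$ linear rate units,

$$\dot r = -r + J r + I(t)\, r_0, \qquad I(t) = \delta(t), \quad \|r_0\| = 1,$$

with the membrane time constant absorbed into the time units. The pulse
input is equivalent to the initial condition $r(0) = r_0$, and the solution
is $r(t) = P_t r_0$ with the **propagator** $P_t = \exp(t(J - I))$.
Stability requires the spectral abscissa of $J$ (the largest real part of
its eigenvalues) to be below 1.

A stable network can still transiently *amplify* selected inputs. The
instantaneous growth rate of the activity norm is the Rayleigh quotient

$$\frac{1}{\|r\|}\frac{d\|r\|}{dt} = \frac{r^T (J_S - I) r}{\|r\|^2},
\qquad J_S = \tfrac{1}{2}(J + J^T),$$

whose maximum over directions is $\lambda_{\max}(J_S) - 1$. Hence the
dichotomy at the core of the package: a stable network has inputs whose
norm transiently rises above its initial value **if and only if**
$\lambda_{\max}(J_S) > 1$. Since $\lambda_{\max}(J_S)$ always dominates the
spectral abscissa, this carves stable couplings into a *monotonic* and an
*amplified* class; only non-normal matrices (eigenvectors not mutually
orthogonal) can be stable yet amplified. `spectral_summary()` implements
the classifier, with an explicit `"boundary"` label within a user margin
$\epsilon$ of the transition so round-off never flips the regime.

The time-resolved input–output structure comes from the SVD of the
propagator, $P_t = \sum_k \sigma_k(t) L_k(t) R_k(t)^T$: inputs along
$R_k(t)$ are mapped onto $L_k(t)$ with gain $\sigma_k(t)$. All
$\sigma_k(0) = 1$, and the initial slopes are $\lambda_k(J_S) - 1$, so the
number of eigenvalues of $J_S$ above $1 + \epsilon$ counts the orthogonal
amplified input directions ($N_S(\epsilon)$, `n_amplified`). The global
optimum over inputs and time is $\sigma_1(t^*)$ (`peak_amplification()`),
and the optimal input satisfies the vanishing-growth-rate condition
$r^T (J_S - I) r = 0$, exposed as `optimality_residual()` — a diagnostic
rather than a solver, because for $N > 2$ the condition does not pin the
optimum down by itself.

## Closed-form ensembles

**Two-population networks** (`two_pop()`, `ei_twopop()`). For
$J = [[a, b], [c, d]]$ the non-normality parameter $\Delta = |b - c|/2$
measures the distance from symmetry; fixing trace and determinant fixes
the eigenvalues $\lambda_\pm$ (hence the timescales
$\tau_\pm = 1/(1 - \mathrm{Re}\,\lambda_\pm)$) while $\Delta$ sweeps the
degree of non-normality. Amplification sets in above
$\Delta_c = \sqrt{\det(J - I)}$. The propagator is evaluated through
$e^{-t}(x_0 I + x_1 J)$, with the eigenvalue-degenerate limit forms
($x_0 = e^{\lambda t}(1 - \lambda t)$, $x_1 = t e^{\lambda t}$) engaged
below a gap of $10^{-8}$; complex eigenvalues are handled in complex
arithmetic and the final quantities must be real to $10^{-10}$ or an error
is raised. The top singular value is
$\sigma_1 = e^{-t}(\sqrt{E^2 + H^2} + |F|)$ in terms of the symmetric-part
spectrum and $\Delta$.

For the asymptotic peak at $\Delta \gg \Delta_c$ we use the form implied by
that envelope: $F \approx H \approx \Delta x_1$, so
$\sigma_1(t) \approx 2\Delta e^{-t} x_1(t)$, peaking at
$t^* = \log\!\big(\tfrac{\lambda_- - 1}{\lambda_+ - 1}\big) /
(\lambda_+ - \lambda_-)$ with value linear in $\Delta$. We validated this
choice against the exact envelope: at $\lambda_\pm = \pm 0.5$, $\Delta = 10$
the asymptotic peak is within 0.3% of the numerically refined maximum,
and `twopop_peak_asymptotic()` always returns the numeric value alongside
for error control.

**Random Gaussian networks** (`gaussian_network()`). With entries of
variance $g^2/N$, the eigenvalues of $J$ fill a disk of radius $g$ and
those of $J_S$ a semicircle of radius $\sqrt{2}\,g$ — so couplings with
$1/\sqrt{2} < g < 1$ are stable yet amplified. Integrating the semicircle
density above $1 + \epsilon$ gives the amplified fraction
(`amplified_fraction_theory()`); at $g = 1$, $\epsilon = 0$ it evaluates to

```{r}
amplified_fraction_theory(0, 1)
```

about 9% of the network size, the maximum over stable coupling scales. The
first-order $\epsilon$-expansion printed in some accounts of this integral
keeps only one of the two $\epsilon$-dependent terms; the package therefore
exposes the exact evaluation and makes no claim about the expansion
coefficient.

**Unit-rank networks** (`lowrank_spec()`, `rank1_analytics()`). For
$J = \Delta u v^T$ with $\|u\| = \|v\| = 1$ and
$\langle u, v\rangle = \rho$, everything is closed-form: the nonzero
eigenvalue $\lambda = \Delta\rho$, symmetric-part eigenvalues
$(\lambda \pm \Delta)/2$ (amplified iff $\Delta(\rho + 1)/2 > 1$ while
$\Delta\rho < 1$), propagator
$P_t = e^{-t}(I + \Delta\,\alpha(t,\lambda)\, u v^T)$ with
$\alpha = (e^{\lambda t} - 1)/\lambda$, the two nontrivial singular values,
the strong-amplification peak $t^* = \log(1/(1-\lambda))/\lambda$ with gain
$g(\lambda)\Delta$, $g(\lambda) = (1-\lambda)^{1/\lambda - 1}$, and the
optimal input/readout pair, which aligns with $v$ and $u$ as $\Delta$
grows. For fixed $\rho < 0$ the peak saturates at $1/|\rho|$. Near
$\lambda = 0$ both $\alpha$ and $g$ switch to series forms below
$|\lambda| < 10^{-6}$ to avoid cancellation ($g(0) = 1/e$, $t^* = 1$).

## Numerical choices

- **Matrix exponentials.** The generic path uses scaling-and-squaring
  (`Matrix::expm`), never eigendecomposition: the flagship examples
  ($\Delta u v^T$ with $u \perp v$, nilpotent two-population cases) are
  defective, and an eigenvector-based exponential would silently lose
  accuracy exactly where the theory is most interesting. Where only
  $e^{tA} x$ is needed at large $N$ (Monte-Carlo experiments), a
  Taylor-with-scaling action routine avoids forming the full exponential.
- **Trajectories.** `simulate_impulse()` evaluates states through the
  propagator semigroup (one exponential per distinct grid step), so
  deterministic trajectories carry no discretization error.
- **Peak search.** $\sigma_1(t)$ need not be unimodal, so
  `peak_amplification()` scans a 200-point grid on
  $[0,\ 10/(1 - \text{spectral abscissa})]$ before golden-section
  refinement to $10^{-6}$, auto-extending once (with a warning) if the
  maximum lands on the horizon.
- **Sign conventions.** Singular vectors are fixed by making the
  largest-magnitude entry of each input vector positive, with the readout
  sign following from $P_t R_k = \sigma_k L_k$; SV trajectories are sorted
  per time point with no mode tracking, so crossings appear as kinks.
  Within numerically degenerate singular blocks (e.g. several identical
  stored channels) only the spanned subspace is well defined; tests and
  downstream code compare spans, not individual vectors.
- **Stochastic integration.** The noisy readout simulation
  (`simulate_readout()`) uses an exponential Euler–Maruyama scheme: the
  drift advances by the exact one-step propagator $e^{(J-I)dt}$ and the
  input noise enters as increments of standard deviation
  $\sigma\sqrt{dt}$, with $dt = 0.01$ by default. A plain first-order
  Euler drift at this step size leaves an $O(10^{-3}$–$10^{-2})$
  deterministic bias on the reference trajectories, an order of magnitude
  above the bias budget we impose ($\sigma = 0$ paths within $10^{-3}$ of
  the exact propagator path), which the exponential step satisfies by
  construction; its $O(dt)$ variance discretization error is well inside
  the Monte-Carlo bands used in the comparisons.

## Robustness and capacity

For $J = \Delta u v^T + g\chi$ (structured part plus i.i.d. Gaussian noise
of entry variance $g^2/N$), the rightmost eigenvalue of $J_S$ follows the
outlier law $(\lambda + \Delta)/2 + g^2/(\lambda + \Delta)$ above the bulk
edge $\sqrt{2}g$ (`noisy_rank1_spectrum()`), shifting the amplification
boundary to $\lambda + \Delta > 1 + \sqrt{1 - 2g^2}$; for
$\sqrt{2} g > 1$ the bulk itself is supercritical and every parameter
choice is amplified.

The readout fluctuation theory (`readout_noise_theory()`) gives the
variance of $u^T r(t^*)$ at the peak ($t^* = 1$ for $\rho \simeq 0$):
$(g^2/N)e^{-2}(\Delta^4/36 + \Delta^2/2 + 1)$ from connectivity noise and
$\sigma^2[1/2 - e^{-2}/2 + \Delta^2(1/4 - (5/4)e^{-2})]$ from input noise.
The Monte-Carlo counterpart (`readout_variance_mc()`) holds the structured
pair fixed (exactly orthonormalized) and resamples only $\chi$: the theory
conditions on the structured part, and resampling $u, v$ would add
$O(\Delta^2/N)$ norm-fluctuation variance an order of magnitude above the
quantity being measured. The readout SNR is
$(\Delta/e)/\sqrt{\mathrm{var}_{\mathrm{input}}}$; it saturates at large
$\Delta$, and `snr_profile()` reports the exact value, the large-$\Delta$
limit and the baseline $1/\sigma$. The critical noise level printed for
the large-$\Delta$ limit differs between the finite-$\Delta$ and limiting
evaluations (≈1.17 near $\Delta \approx 5$ vs ≈1.29 in the strict limit),
so the package reports the profile and asserts only the ordering
$SNR(\Delta = 4) > SNR(\Delta = 1)$.

Storing $P$ patterns makes the other $P - 1$ act as effective connectivity
noise of entry variance $\Delta^2 P/N^2$
(`crosstalk_experiment()`); the bulk spectrum fills a disk of radius
$\Delta\sqrt{P/N}$, so stability caps the load at
$P_{\max} = \lfloor N/\Delta^2\rfloor$ (`capacity()`), and since
uncorrelated patterns amplify only for $\Delta > 2$, an amplified network
stores at most $N/4$ channels.

## What the generators emulate — and what they do not

The built-in ensembles *are* the study conditions of the theory: Gaussian
couplings with variance $g^2/N$, structure vectors with entries of
variance $1/N$ (unit norm on average, correlation $\rho$), white input
noise, instantaneous pulse inputs. Two vector-generation modes exist
because the theory itself alternates between them: `"sampled"` follows the
Gaussian recipe literally (norms fluctuate at $O(1/\sqrt{N})$), `"exact"`
Gram-Schmidt-corrects to exact unit norms, exact $\rho$ and exact
cross-pattern orthogonality — the deterministic geometry assumed by the
closed forms, and the default in unit tests and designed channels. None of
the generators model structured biological connectivity (Dale's law,
sparse topology), temporally extended inputs, or nonlinear rates, so
passing tests certify the linear theory under its own assumptions, not its
fit to recordings.

## Problem sizes and determinism

The test-suite and acceptance experiments run at reduced size relative to
the largest analyses one would publish with this machinery: random-matrix
radii at $N = 2000$, the amplified-fraction cross-check at $N = 4000$ (one
draw), readout-variance Monte-Carlo at $N \in \{200, 400, 800\}$ with up
to 1000 connectivity realizations (enough to hold the Monte-Carlo error on
the fitted $1/N$ slope near 0.05), and cross-talk scaling at
$N \in \{200, 800\}$. These sizes keep every experiment deterministic
under a fixed seed and reproducible in minutes on a single core while
leaving the asymptotic laws clearly resolved. Every stochastic entry point
takes an explicit seed; the command-line layer logs the configuration and
seed of every run.

## Known limitations

- The asymptotic two-population peak formula assumes real, distinct stable
  eigenvalues; complex pairs must use the numeric path
  (`peak_amplification()`), which is always available.
- $N_S(\epsilon)$ is a small-time lower bound on the number of amplified
  directions; at later times singular values may cross unity in either
  direction.
- The rank-1 fluctuation theory is first-order in $g$ and derived for
  $\rho \simeq 0$ in the strong-amplification regime; outside that regime
  the package still simulates, but flags the theory fields as
  extrapolations.
- Pseudospectral bounds, nonlinear transient coding and sign-constrained
  (excitatory/inhibitory) constructions of low-rank channels are out of
  scope; the rank-$k$ feed-forward-chain extension for prolonged
  transients is a documented extension point, not implemented.
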