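---
title: "Contraction analysis of plastic recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contraction analysis of plastic recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contractnet)
```

## The model and what "stable" means here

`contractnet` studies recurrent rate networks of the form

$$\dot x_i = h_i(x_i) + \sum_j W_{ij}\, r(x_j) + u_i(t),$$

where $x_i$ is the deviation of neuron $i$ from a positive baseline rate (so
$x_i$ may be negative and no rectification is applied), $h_i$ is a leak with
$h_i' < 0$ everywhere (default $h_i(x) = -\beta_i x$ with $\beta_i = 1$),
$r$ is the activation (identity for the linear-rate model, `tanh` for the
saturating one), and $u_i(t)$ is an arbitrary finite input.  Self-feedback is
carried by the leak, so generated weight matrices have a zero diagonal.
Synapses are dynamical variables on an equal footing with the neurons:

$$\dot W_{ij} = -k_{ij}\, x_i x_j - \gamma(t)\, W_{ij},$$

a correlational rule (Hebbian for inhibitory synapses, anti-Hebbian for
excitatory ones — `classify_plasticity_effect()` tabulates the four sign
cases) with forgetting rate $\gamma > 0$.  The combined state
$[x;\, \mathrm{rows\ of}\ W]$ lives in $n + n^2$ dimensions.

The stability notion is *contraction*: every pair of trajectories converges
exponentially toward each other, in some metric, regardless of initial
conditions.  This is stronger and more useful than eigenvalue stability of a
fixed point — it applies to input-driven, time-varying trajectories, and it
composes across interconnected subsystems.  The workhorse quantity is the
logarithmic norm (matrix measure) of the Jacobian $J$: if
$\mu(J) \le -c < 0$ along trajectories, separations shrink at rate at least
$c$.  The package implements the closed forms

$$\mu_1(A) = \max_j \Big[a_{jj} + \sum_{i \ne j} |a_{ij}|\Big], \qquad
  \mu_2(A) = \lambda_{\max}\!\Big(\tfrac{A^T + A}{2}\Big),$$

keeping the limit-definition quotient `mu_limit_oracle()` purely as an
independent numerical check (one-sided difference at fixed
$\epsilon = 10^{-7}$; no extrapolation, because it is a test oracle, not a
production path).  $\mu_1$ is column-indexed: conventions differ across
texts, and the induced 1-norm here is the maximum absolute *column* sum.

Why eigenvalues are not enough: the package ships a time-varying
counterexample, $\dot x = -x + e^{2t} y$, $\dot y = -y$, whose system matrix
has eigenvalues fixed at $(-1, -1)$ for all $t$ while the solution grows as
$\sinh(t)$.  (The eigenvalues follow from the triangular structure; they are
consistent with the printed solution $y = y(0)e^{-t}$.)  The symmetric part
is what matters: $\mu_2(A(t)) = -1 + e^{2t}/2$ crosses zero at
$t = \ln(2)/2$, and `eigenvalue_test_insufficiency_demo()` verifies all of
this numerically against the closed form.

## Metrics and transient divergence

A coordinate change $y = \theta x$ induces the metric $M = \theta^T\theta$;
contraction in any one metric implies convergence in all coordinates,
possibly after transient divergence in the original ones.  The package makes
this concrete: for $A = \begin{pmatrix}-1 & 10\\ 0 & -1\end{pmatrix}$,
$\mu_2(A) = +4$ in the identity metric but $-0.5$ under
$\theta = \mathrm{diag}(1, 10)$, and simulated twin trajectories show the
corresponding transient Euclidean-distance growth with monotone decay in the
transformed norm.

## The certificates

**Plasticity hypotheses.**  The contraction theorem for the correlational
rule requires the learning-rate matrix $K$ to be symmetric, entrywise
positive, and positive semi-definite; `check_plasticity_hypotheses()` tests
all three (symmetry to relative $10^{-10}$; PSD to
$\lambda_{\min} \ge -10^{-10}\|K\|$).  The equal-rate case
$K = k\,\mathbf{1}\mathbf{1}^T$ is the canonical example (rank-1 PSD).

**The plasticity certificate and its metric.**
`hebbian_contraction_certificate()` certifies the combined
$(n + n^2)$-dimensional system for the linear-rate model.  The metric was a
genuinely open design choice: the derivation that produces it from $K$ is
not part of the distributed analysis, so the package uses the diagonal
rescaling $\theta = \mathrm{diag}(I_n,\, 1/\sqrt{k_{ij}})$ on the synaptic
coordinates.  This is the natural scaling that makes the neural-to-synaptic
and synaptic-to-neural Jacobian cross-blocks (nearly) equal-and-opposite —
the negative-feedback structure that preserves contraction when contracting
subsystems are reciprocally coupled.  Crucially, the certificate does not
*assume* the metric works: it simulates an input-free test trajectory
(default 10 time units, 50 Jacobian samples) and verifies
$\mu_2(\theta J \theta^{-1}) < 0$ numerically, reporting the metric as an
implementation choice in the report.

The negativity check applies to the *tail* of the test trajectory (default:
after a 50% burn-in).  This is not a fudge but a property of the system:
with $W(0)$ drawn uniformly from $[-1, 1]^{n \times n}$,
$\lambda_{\max}(\mathrm{sym}\,W(0))$ scales like $\sqrt{n}$ and exceeds the
leak rate, so *any* fixed metric sees positive $\mu_2$ during the transient
in which the plasticity is still driving the weights down.  What the theory
promises — and what the diagnostics verify — is that the plasticity
symmetrizes $W$ (the antisymmetric part obeys
$\|{\rm antisym}\,W(t)\| = \|{\rm antisym}\,W(0)\|e^{-\int\gamma}$ exactly
when $K$ is symmetric) and drives $\lambda_{\max}(\mathrm{sym}\,W)$ below
$\beta$, after which $\mu_2 < 0$ holds and trajectories collapse together.
With $\gamma = 0$ the synaptic Jacobian block loses its $-\gamma I$ and the
certificate correctly fails.

**The symmetric-part bound curve.**  `weight_spectral_trace()` reports
$\lambda_{\max}(\mathrm{sym}\,W(t))$ together with the bound
$\lambda_{\max}(\mathrm{sym}\,W(0))\,e^{-\int_0^t \gamma}$.  The bound is
implementation-derived but provable under the certificate's own hypotheses:
an entrywise-positive PSD $K$ makes $K \circ xx^T$ PSD (Schur product
theorem), so the symmetric part's drive is negative semi-definite and
forgetting dominates.  `bound_check()` tests the contraction prerequisite
$\lambda_{\max}(\mathrm{sym}\,W(t)) \le \min_i \beta_i$ after a 10% burn-in.

**Sparsity.**  For networks where a fraction $\alpha_i$ of each neuron's
$p_i$ afferent synapses is plastic (with forgetting), the per-neuron
inequality

$$p_i\,(g_{\max} w_{\max} + \alpha_i r_{\max}) < \beta_i$$

certifies global contraction.  `sparsity_certificate()` returns the margins
$\beta_i - p_i(g_{\max}w_{\max} + \alpha_i r_{\max})$, which are exactly
affine in $p_i$ with slope $-g_{\max}w_{\max}$ when $\alpha = 0$.  The
derivation assumes a bounded activation wherever synapses are plastic, so
$\alpha_i > 0$ with the identity activation (unbounded $r_{\max}$) is
rejected as a precondition error rather than silently producing $-\infty$
margins.  The forgetting assumption on plastic synapses is identified with
$\gamma > 0$ of the plasticity rule.

**E-I balance.**  For static weights, contraction is decided by
$\lambda_{\max}(\mathrm{sym}\,W) < \min_i\beta_i / g_{\max}$
(`static_symmetric_part_certificate()`).  Cross-population blocks satisfying
$W_{EI} = -W_{IE}^T$ cancel identically in the symmetric part, so balanced
excitatory-inhibitory coupling cannot destabilize the network at *any*
amplitude; `ei_balance_certificate()` checks the Dale sign conventions, the
cancellation residual, and then the symmetric-part test on the full matrix
(any residual is thereby folded into the test automatically).  The residual
is measured in the spectral norm, because that is what bounds the residual's
contribution to $\lambda_{\max}(\mathrm{sym}\,W)$, and because for
"statistical" balance (independent blocks with matched mean amplitudes) the
spectral-norm residual shrinks as $1/\sqrt{n}$ while the Frobenius residual
does not shrink at all.  The default statistical tolerance is 5%; no
canonical value exists, and callers probing statistical balance at moderate
$n$ should set it from the fixture's own residual scale.

**Echo-state check.**  Discrete-time reservoirs $x^+ = r(Wx + u)$ with gain
$\le g_{\max}$ are contracting when $g_{\max}\sigma_{\max}(W) < 1$
(`esn_discrete_contraction_check()`).  This is a different update rule from
the continuous-time model, so the `certify` command reports it only on
request rather than letting it veto the continuous-time verdict.

## Numerics

*Integration.*  Deterministic runs use classical fixed-step RK4; stochastic
runs use Euler–Maruyama with independent Wiener increments applied to the
neural coordinates only (noise never drives the weights directly), and with
zero noise Euler–Maruyama reduces exactly to forward Euler.  The default
step is $dt = 10^{-2}$, the protocol value for figure-style runs;
quantitative closed-form checks use $10^{-3}$ (and the counterexample demo
$10^{-4}$), where RK4's $O(dt^4)$ error is far below the 1% assertion
tolerances.  Any non-finite state aborts with the blow-up time.  Recording
can be thinned (`record_every`) so that $n = 100$ combined-system runs
(state dimension 10100) stay within tens of megabytes.

*Large-scale $\mu_2$.*  The metric-transformed Jacobian at $n = 100$ is a
$10100 \times 10100$ operator; the certificate evaluates
$\lambda_{\max}$ of its symmetric part matrix-free (the matvec costs
$O(n^2)$) with an in-package Lanczos iteration using full
reorthogonalization and a deterministic start vector, switching to a dense
symmetric eigensolver below dimension 1500.  Dense and matrix-free routes
agree to $10^{-9}$ in tests.  Symmetric parts are always fed to symmetric
eigensolvers (`eigen(symmetric = TRUE)`), never to the general solver.

*Contraction-rate fits.*  `estimate_contraction_rate()` is an ordinary
least-squares fit of $\log d(t)$ against $t$ — distances must be strictly
positive on the window, and a constant series returns rate 0 with
$r^2 = 1$ (the zero-slope model fits exactly; the usual $R^2$ is undefined
when the total sum of squares vanishes).  A contraction *rate* is only
meaningful while $\mu$ stays negative, so certificates expose margins
($-\mu_2$ on the trajectory tail) and report no rate when negativity fails.

*Reproducibility.*  Every stochastic ingredient (initial conditions, input
banks, noise, fixture wiring) is drawn through seeded draws that snapshot
and restore the global RNG, so package calls never perturb a user's random
stream, and equal seeds give bit-identical runs.

## What the generators emulate — and what they do not

The fixtures module is the package's synthetic-data surface and encodes the
reference study conditions: all rates and time constants equal to one,
initial activations and weights uniform on $[-1, 1]$ (zero weight
diagonal), per-neuron sinusoid inputs with frequencies on $[dt, 100\,dt]$,
phases on $[0, 2\pi)$ and amplitudes on $[0, 20]$, a pulse of value 10 for
100 steps starting mid-run, and noise $\sigma = 0.2$.  The sinusoid
frequency range is tied to the integration step verbatim for protocol
fidelity, dimensionally odd as that is; `physical_units = TRUE` offers an
absolute range instead.  Two sizes are fixed by choice rather than by the
protocol, which does not print them: distance/spectral reproductions use
$n = 100$ and a horizon of 20 time units, large enough that certified runs
reach a terminal distance below $10^{-3}$ of the initial separation while a
full pipeline completes in seconds; the step-size and antisymmetric-decay
checks use $n = 20$ at $dt = 10^{-3}$.

These fixtures are idealizations.  Passing tests on them shows that the
implementation realizes the theory's mechanisms — exact antisymmetric decay,
certificate soundness confirmed by trajectory convergence, amplitude-
invariant E-I balance — not that real circuits satisfy the hypotheses: actual
cortical connectivity is not uniform-random, learning rates are not all
equal, synapses are signed and bounded, and real noise is neither white nor
purely additive.  The certificates themselves accept arbitrary user-supplied
matrices and parameter sets, which is where empirical use belongs.

## Known limitations

- The plasticity certificate covers the linear-rate model (identity
  activation); the saturating model is certified through the sparsity or
  static routes instead.
- Only $p \in \{1, 2\}$ logarithmic norms and real-valued matrices are
  implemented.
- The certificate's trajectory check is numerical evidence along sampled
  trajectories, not a symbolic proof; margins quantify how much room the
  sampled Jacobians had.
- No adaptive or stiff solvers, delays, or spiking dynamics; fixed-step
  integration is the contract.
- Region-of-contraction estimation for arbitrary trained networks is out of
  scope.
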