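---
title: "Symmetry-reduced simulation of ZULF SABRE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-reduced simulation of ZULF SABRE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical model

SABRE (signal amplification by reversible exchange) transfers the singlet
spin order of parahydrogen to a substrate through its transient binding to
an Ir-dihydride complex. At zero and ultralow magnetic field (ZULF), the
spin dynamics is governed by the low-field Hamiltonian

$$
\hat H(t) \;=\; -B_0(t)\sum_l \gamma_l \hat I_{zl}
\;+\; 2\pi \sum_{l<m} J_{lm}\,(\hat I_l\cdot\hat I_m),
$$

in angular-frequency units: the Zeeman term carries no $2\pi$ (the
$\gamma_l$ are in rad s$^{-1}$ T$^{-1}$), while the $J$ couplings are
entered in Hz. Chemical shifts are neglected by default, as appropriate at
microtesla fields; a per-nucleus isotropic shift in ppm can be supplied
and is folded into the Zeeman term.

Three processes are treated on an equal footing in Liouville space:

1. **Coherent evolution** by the commutation superoperator
   $\hat{\hat H} = \hat H\otimes \mathbb 1 - \mathbb 1\otimes \hat H^{\top}$
   (row-major vectorization, so the Kronecker formula is literal).
2. **Relaxation** by the random-fluctuating-field (RFF) Redfield
   superoperator in the extreme-narrowing limit,
   $\hat{\hat\Gamma} = -\tfrac12\sum_{n,l} \tfrac{C_{nl}}{\sqrt{T_{1n}T_{1l}}}
   \sum_m (-1)^m \hat{\hat T}_{1,-m}^{(n)}\hat{\hat T}_{1,m}^{(l)}$,
   with isotropic local fields, so $T_2=T_1$ per spin. The correlation
   matrix defaults to fully correlated fields within a group of
   magnetically equivalent nuclei and uncorrelated fields otherwise; a
   general $C_{nl}\in[0,1]$ may be supplied.
3. **Reversible chemical exchange** between the free-substrate and complex
   pools, linear in the densities: dissociation at rate constant $k_d$
   maps the complex onto the substrate by a partial trace over the two
   hydrides, and association at rate $W_a = k_d\,[C]/[S]$ attaches a fresh
   parahydrogen singlet by a Kronecker product. The density matrices carry
   concentration normalization, $\mathrm{tr}\,\rho^S = [S]/([C]+[S])$ and
   $\mathrm{tr}\,\rho^C = [C]/([C]+[S])$; their sum is conserved exactly
   (the global trace functional is a left null vector of the assembled
   generator, which the tests verify).

The model is linear (fast parahydrogen supply and fast dihydrogen
exchange); nonlinear SABRE kinetics, RF pulses, and relaxation mechanisms
beyond the RFF model (dipole-dipole, CSA, cross-correlations) are out of
scope. Exchange continues during signal acquisition, reflecting continuous
parahydrogen bubbling in the two-stage experiment.

## The two symmetry reductions

**Effective spins.** A group of $P$ magnetically equivalent spin-1/2
nuclei (all external couplings identical across members, enforced at
validation with relative tolerance $10^{-9}$) is replaced by one effective
spin $K \in \{P/2, P/2-1, \dots, K_{\min}\}$ with
$K_{\min}=0$ ($P$ even) or $1/2$ ($P$ odd). Each configuration carries the
statistical weight $g_K = (2K+1)\mu_K/2^P$, where the multiplicity
$\mu_K = \binom{P}{P/2-K} - \binom{P}{P/2-K-1}$ is evaluated in exact
integer arithmetic so the weights sum to one exactly. Intra-group
couplings drop out of the reduced Hamiltonian; group members share a $T_1$
and their relaxation enters as a single collective spin-$K$ term. Physical
observables are weight-averaged over the configurations, each propagated
independently.

**Zero-quantum-coherence (ZQC) restriction.** The ket-bra basis element
$|r\rangle\langle c|$ carries coherence order $q = F_z(r)-F_z(c)$. The
Hamiltonian and RFF superoperators commute with the total-$F_z$
superoperator, and both exchange maps conserve $q$, so a density matrix
that starts diagonal (the unpolarized initial condition) never leaves the
$q=0$ subspace. The solver therefore assembles the generator directly on
the ZQC index set, whose dimension is
$\sum_{F_z} \dim(\mathcal H_{F_z})^2$ with per-$F_z$ block sizes given by
the convolution of per-site $m$-degeneracies. For the shipped
6-spin/8-spin acetonitrile model this is $196 + 2838 = 3034$ at $K=3/2$,
against $17\,408$ for the effective-spin-only representation and
$69\,632$ for the unreduced problem; for group-free substrates the
reduction factor approaches $\sqrt{\pi N}$.

Both reductions are exact, not approximations. The package keeps all
three representations (`"full"`, `"k_reduced"`, `"zqc"`) behind one
interface, sharing every operator builder, precisely so that the test
suite can verify this exactness numerically: on the acetonitrile model the
representations agree to a relative residual of order $10^{-11}$ over a
field scan, far inside the $10^{-5}$ documented for this class of solver.

## Numerical choices

* **Vectorization and ordering.** Row-major vec ($|r\rangle\langle c|
  \mapsto (r-1)d+c$); per-site descending-$m$ basis; sites ordered as
  declared, with effective spins appended after the non-equivalent nuclei.
  For a complex the reduced ordering is: reduced substrate sites, then the
  two hydrides (so exchange maps are pure index arithmetic). The ZQC index
  is ordered by ascending $F_z$ block, then ket, then bra; half-integer
  $F_z$ values are handled as doubled integers so block keys are exact.
* **Direct ZQC assembly.** Superoperators are assembled on the restricted
  index sets from per-$F_z$-block Kronecker products (Hamiltonian) and
  products of rectangular coherence-shift blocks (relaxation), without
  materializing the parent Liouville space; exchange blocks are built by
  index hashing. Projection of an explicitly built superoperator is a
  plain row/column gather (the ket-bra basis is orthonormal), and the
  tests confirm the two routes coincide.
* **Propagation.** Each constant-field segment applies the action of the
  matrix exponential. The generators are near-normal (skew-Hermitian
  Hamiltonian part of norm up to $\sim 10^3$-$10^4$ rad/s, dissipative part
  of order $k_d + 1/T_1$), so two schemes are used: a scaled Taylor
  expansion for short steps, and a Chebyshev expansion with Bessel
  coefficients (computed by Miller's downward recurrence) for long
  coherent evolutions, substepped so the dissipative part stays inside the
  expansion's convergence region. Both monitor term decay against the
  requested tolerance (default $10^{-9}$ relative) and restart with more
  steps if convergence is not observed, so accuracy never rests on the
  power-iteration spectral-norm estimate that sizes the steps.
* **Guards.** The unreduced solver refuses models whose Liouville
  dimension $4^N + 4^{N+2}$ exceeds a configurable cap (default $10^6$).
  Observables evaluated in the ZQC representation must be $q=0$-supported;
  anything else (e.g. $\hat I_x$) raises an error rather than silently
  reporting a biased value.

## Shipped models and parameter provenance

Two models are shipped as structured text files with unit-suffixed keys
(`j_hz`, `t1_s`, `kd_s1`): a 6-spin [15N,13C2]acetonitrile substrate
(8-spin complex) and a 12-spin [15N,13C4]butyronitrile substrate (14-spin
complex). The coupling constants combine values quoted for these
isotopologues ($^1J_{\mathrm{CH}} = 136$ Hz, $^1J_{\mathrm{CN}} = -18$ Hz,
and $^1J_{\mathrm{CC}} = 56$ Hz with $^2J_{\mathrm{CH}} = -5.2$ Hz
recovered from quoted first-order ZULF line positions) with standard
literature values for the remaining couplings. The hydride parameters
($J_{\mathrm{HH'}} = -7$ Hz, trans $J_{\mathrm{NH}} = -24$ Hz, $T_1$ of
1.5 s in the complex) and all $T_1$ values are typical of Ir-IMes SABRE
chemistry but are *reconstructions*, not measured values for these exact
complexes; files document the provenance of each number. Consequences:
dimension counts, statistical weights, reduction exactness and the
qualitative shape of the field dependence (broad profiles over 0-3 uT,
multiple extrema, sign changes, maxima in the few-tenths-of-a-microtesla
region) are insensitive to these choices, but the precise field at which
each nucleus's polarization peaks shifts by one or two tenths of a
microtesla with the hydride coupling set, and with the shipped values not
every nucleus peaks in the same 0.1 uT grid cell near 0.5 uT.

The random-system generator used by the property tests draws spin systems
of 2-5 sites with couplings uniform in $\pm 20$ Hz and $T_1$ between 1 and
10 s, optionally containing one equivalence group whose external couplings
are made identical by construction. It emulates the coupling-network
topology and relaxation scales of small heteronuclear molecules; it does
not emulate chemical-shift dispersion, quadrupolar nuclei, or correlated
relaxation between non-equivalent sites, so passing property tests speak
to the algebraic structure of the solver, not to quantitative agreement
with any particular real compound.

## Problem sizes used in the checks

The validation suite runs at desk scale on one CPU: the three-way
representation comparison uses the 6-spin/8-spin acetonitrile model at
five fields with $t_{\mathrm{pol}} = 1$ s (the unreduced solve is a
69 632-dimensional state, about half a minute per field); the optimal-field
profile uses the ZQC path on a 31-point, 0-3 uT grid; FID checks use a
2-spin substrate and, for the shipped model, shortened polarization and
acquisition windows relative to the 10 s + 5 s two-stage protocol, which
leave the line positions unchanged. The 12-spin butyronitrile model is
exercised through its exact dimension and weight tables and a three-field
smoke run of the smallest effective-spin configuration
($K_1{=}0, K_2{=}0, K_3{=}1/2$; ZQC dimension $924+12\,870$); its largest
configuration (ZQC dimension $\sim 3\times 10^6$) is within the design's
reach through the same code path but takes hours per field point, which is
the regime the reduction exists for rather than a test-suite workload.

## Known limitations

* Physical nuclei are restricted to spin 1/2 (no quadrupolar isotopes);
  arbitrary spins occur only as effective group spins.
* One substrate binding site; hydride exchange kinetics are folded into
  the linear two-pool model.
* The RFF model is the only relaxation mechanism; mechanisms sharing the
  same symmetry (dipolar, axial CSA) would slot into the same interface
  but are not implemented.
* Strictly zero field ($B_0 \equiv 0$) possesses additional rotational
  symmetry that is deliberately not exploited; simulations there simply
  run with the ultralow-field machinery.

## Interface shape

Result-bearing functions (`field_scan()`, `average_configs()`,
`simulate_fid()`, `spectrum()`, `matrix_dimensions()`,
`bench_dimensions()`) return tibbles and compose with the pipe;
`autoplot()` methods cover scans, FIDs and spectra, and `tidy()`/
`glance()` summarize models. The operator layer underneath is base R plus
sparse `Matrix` algebra with a compiled propagation core, which is the
natural shape for Liouville-space machinery. A thin command-line wrapper
(`inst/cli/zulfsabre`) exposes `dims`, `validate`, `fieldscan`,
`spectrum` and `bench` subcommands over the same functions.
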