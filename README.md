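# zulfsabre

Simulation of SABRE hyperpolarization at zero and ultralow magnetic field
(ZULF), for NMR spectroscopists who want quantitative, predictive models of
microtesla polarization transfer: optimal polarization fields, polarization
build-up, and ZULF J-spectra of multi-spin heteronuclear substrates.

SABRE (signal amplification by reversible exchange) transfers the singlet
order of parahydrogen to a substrate that reversibly binds to an
Ir-dihydride complex. The package integrates the coupled master equation
for the free-substrate and complex density matrices,

    drho_S/dt = (L_S - Wa) rho_S + kd Tr_H2 rho_C
    drho_C/dt = (L_C - kd) rho_C + Wa (rho_S ⊗ rho_pH2),

with `L = -i H + Γ` the Liouvillian built from the low-field Hamiltonian
`H = -B0 Σ γ_l Iz_l + 2π Σ J_lm (I_l · I_m)` and the random-fluctuating-
field Redfield relaxation superoperator Γ (extreme narrowing, T2 = T1),
`kd` the dissociation rate constant and `Wa = kd [C]/[S]`.

Two exact symmetry reductions make multi-spin systems tractable:

* **Effective spins** — each group of P magnetically equivalent protons is
  replaced by one spin K ∈ {P/2, …, Kmin} with exact statistical weight
  `g_K = (2K+1) μ_K / 2^P`, and results are weight-averaged over the
  configurations.
* **Zero-quantum-coherence (ZQC) restriction** — Hamiltonian, relaxation
  and both exchange maps conserve the coherence order
  `q = Fz(ket) − Fz(bra)`, so the dynamics never leaves the q = 0
  subspace, whose dimension is smaller than the 4^N Liouville space by a
  factor approaching √(πN).

Unreduced (`"full"`) and effective-spin-only (`"k_reduced"`) reference
solvers share every operator builder with the ZQC path and are used to
verify that the reductions are exact.

## Worked example

The shipped [15N,13C2]acetonitrile model (6 substrate spins: 1-15N, 2-13C,
3-13C and a CH3 group; 8-spin complex with two hydrides):

```r
library(zulfsabre)

model <- sabre_fixture("acetonitrile_15N13C2")
#> <sabre_model> substrate 6 spins, complex 8 spins; kd = 10 /s, [C]/[S] = 0.1

matrix_dimensions(model)
#> # A tibble: 2 × 6
#>   config  weight k_reduced zqc_substrate zqc_complex   zqc
#>   <chr>    <dbl>     <dbl>         <int>       <int> <int>
#> 1 CH3=3/2    0.5     17408           196        2838  3034
#> 2 CH3=1/2    0.5      4352            70         924   994
```

The unreduced problem has dimension 4^6 + 4^8 = 69 632; the effective-spin
representation needs at most 17 408, and the ZQC representation 3034 —
the reduction the package exists for. The two CH3 configurations carry
equal weights 1/2.

A polarization field scan (1 s of polarization at each field, weights
applied by `average_configs()`; polarization is the dimensionless
per-nucleus ⟨Iz⟩, range ±1/2):

```r
scan <- field_scan(model, fields = c(0.3, 0.5, 1.0) * 1e-6, tpol = 1)
average_configs(scan)
#> # A tibble: 12 × 3
#>         b0_t nucleus polarization
#>        <dbl> <chr>          <dbl>
#>  1 0.0000003 C2          0.00880
#>  2 0.0000003 C3          0.00483
#>  3 0.0000003 CH3         0.00325
#>  4 0.0000003 N1          0.0250
#>  5 0.0000005 C2          0.0131
#>  6 0.0000005 C3          0.00289
#>  7 0.0000005 CH3         0.00237
#>  8 0.0000005 N1          0.0214
#>  9 0.000001  C2          0.00967
#> 10 0.000001  C3          0.00284
#> 11 0.000001  N1          0.00343
#> 12 0.000001  CH3         0.000167
```

So after 1 s at 0.3 µT the free 15N pool carries 2.5 % polarization —
a four-orders-of-magnitude enhancement over thermal microtesla
polarization. `autoplot()` renders scans, FIDs (`simulate_fid()`, the
two-stage polarize-then-detect protocol) and spectra (`spectrum()`);
`solve_full()` / `solve_k_reduced()` / `solve_zqc()` give the three-way
validation at one field. A command-line wrapper with `dims`, `validate`,
`fieldscan`, `spectrum` and `bench` subcommands lives in
`inst/cli/zulfsabre`.

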