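---
title: "Modelling DNA crossbar read-out: transport, circuits, and error rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA crossbar read-out: transport, circuits, and error rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

dnarom simulates an electrically readable read-only memory in which every
crossbar junction holds a double-stranded DNA molecule. Two sequences with
different conductance encode logic 0 and logic 1; reading a row means biasing
its wordline and recording the currents that reach the grounded bitlines.
The package covers the full chain from molecular Hamiltonian to bit error
rate: a decoherent quantum-transport engine produces current-voltage lookup
tables for each species, and a nonlinear circuit layer turns those tables
into read-out maps, Monte Carlo error-rate distributions, and power figures.
This vignette explains the models, their assumptions, the tunable parameters,
and the numerical choices, in the order the pipeline runs them.

## From electronic structure to a blocked Hamiltonian

The transport engine takes a real symmetric Hamiltonian whose basis is
grouped into nucleotide blocks. Starting from quantum-chemistry output - a
Fock matrix $F$ (eV) and overlap matrix $S$ in an atomic-orbital basis -
`lowdin_orthogonalize()` forms the symmetric orthogonalization

$$H_a = S^{-1/2}\, F\, S^{-1/2},$$

which preserves the generalized spectrum of $(F, S)$; a non-positive-definite
overlap is rejected with the offending eigenvalue named.
`block_diagonalize()` then rotates each nucleotide's diagonal sub-block onto
its own eigenbasis, $H_b = U^{\mathsf T} H_a U$, with $U$ assembled
nucleotide-by-nucleotide. The diagonal entries of each diagonal block of
$H_b$ are molecular-orbital energies of that nucleotide; off-diagonal blocks
are electronic couplings between nucleotides. Eigenvectors are ordered by
ascending eigenvalue with the sign fixed so each vector's largest-magnitude
component is positive, which makes $U$ deterministic; within a degenerate
eigenvalue cluster $H_b$ is unique only up to a rotation that no
spectrum-level quantity sees.

A bias $V_\mathrm{bias}$ enters through a fixed potential profile rather
than a self-consistent electrostatic solve: 40% of the voltage drops at each
contact and the remaining 20% falls linearly along the interior base pairs,

$$V_n = \begin{cases} 0 & n = 1\\
V_\mathrm{bias}\bigl(0.4 + 0.2\,(n-2)/(N-3)\bigr) & 2 \le n \le N-1\\
V_\mathrm{bias} & n = N,\end{cases}$$

and `apply_bias_ramp()` adds $qV_n$ to every diagonal entry of both
nucleotide blocks of base pair $n$ (the ramp is indexed by base pair, and the
base-pair grouping metadata carries the pairing). The interior formula
divides by $N-3$, so duplexes shorter than four base pairs are rejected
rather than guessed at.

## Decoherent transport and the Landauer current

Charge transport through DNA at room temperature is partially phase-broken.
The engine models this with fictitious dephasing probes: wide-band
self-energies $-i\Gamma_{L(R)}/2$ on the 3' and 5' terminal nucleotides
(default $\Gamma_{L(R)} = 1$ eV) and $-i\Gamma_k/2$ on every other
nucleotide (default $\Gamma_k = 10$ meV). The retarded Green's function
solves

$$\bigl[E - (H_b + \Sigma_L + \Sigma_R + \Sigma_B)\bigr] G^r = I,$$

and terminal-to-terminal transmissions are
$T_{kl} = \mathrm{Tr}\,\Gamma_k G^r \Gamma_l G^a$, where the trace runs over
the orbitals of the receiving block (for one orbital per site this is the
familiar scalar $\gamma_k\gamma_l |G^r_{kl}|^2$). Each probe must carry zero
net current at every energy; eliminating the probe occupations through the
matrix $W_{kl} = (1-R_{kk})\delta_{kl} - T_{kl}(1-\delta_{kl})$, with
$R_{kk}$ the reflection probability, leaves the effective transmission

$$T_\mathrm{eff}(E) = T_{LR} + \sum_{k,l} T_{Lk}\, W^{-1}_{kl}\, T_{lR},$$

the coherent term plus the probe-mediated incoherent contribution. $W$ is
applied through a linear solve, never an explicit inverse, and its
reciprocal condition number is attached to the result. With no probes
$T_\mathrm{eff} = T_{LR}$ exactly, and as $\Gamma_k \to 0$ it approaches
$T_{LR}$ pointwise - both limits are tested.

The terminal current uses the Landauer form with the probe-eliminated
transmission,

$$I = \frac{2q^2}{h} \int T_\mathrm{eff}(E)\,
\bigl[f_R(E) - f_L(E)\bigr]\, \mathrm dE,
\qquad E_{fR} = E_{fL} + qV_\mathrm{bias},$$

with Fermi functions at $kT = 0.0259$ eV (300 K; the temperature is
configurable). Writing the window factor as $f_R - f_L$ makes the current
positive for positive bias through a conducting channel. Integration is
trapezoidal on a uniform grid (default step 1 meV, fine enough to resolve
the 10 meV probe broadening) spanning the Fermi window plus a $10\,kT$
margin on each side; a grid that fails to cover the window raises an error
rather than silently truncating. The suite verifies this machinery against
closed forms that never touch the implementation: the single-site Lorentzian
junction (transmission exact to $10^{-10}$; finite-temperature current
against a digamma-series evaluation of the Lorentzian-Fermi integral to
0.1%), a hand-inverted two-site chain, a hand-solved single-probe balance,
energy-resolved probe-current cancellation, and $I_L + I_R = 0$.

`iv_sweep()` tabulates the current over a bias grid and a grid of Fermi
offsets $\delta$: the left-contact Fermi energy sits $\delta$ eV above the
HOMO anchor, emulating contact-induced level shifts. Because the
transmission does not depend on $\delta$, each bias point computes one
spectrum and integrates it once per offset. The resulting `iv_table` is the
hand-off between the physics and the circuit layers.

## The surrogate duplexes

The quantum-chemistry matrices of the two experimental sequences are not
publicly deposited, so the package ships a calibrated tight-binding
surrogate (`surrogate_spec()`, `surrogate_hamiltonian()`): a two-leg ladder
of 7 base pairs in which every nucleotide carries five HOMO-manifold
orbitals spread over ~0.5 eV, with stacking couplings of 0.22 eV between
interior base pairs, 0.08 eV rungs, and weak contact-side bonds that set the
conductance scale (0.62 meV for the CT1C-like logic-1 species, 0.22 meV for
the TC1T-like logic-0 species; deeper orbital channels carry
proportionally stronger contact weight). A deterministic incommensurate
jitter (20 meV) plus a seeded 5 meV disorder breaks level degeneracies the
same way for every seed. After generation the diagonal is rigidly shifted so
the zero-bias HOMO peak sits at -5.2 eV, and the fixture contract
(`check_iv_contract()`) is enforced: peak location within 50 meV; zero
current at zero bias; mega-Ohm-scale zero-bias secant resistance (the
defaults give ~58 MOhm and ~460 MOhm); roughly an order of magnitude current
contrast at 1 V (~3.0 nA vs ~0.37 nA, matching the nanoamp threshold scale
the device concept implies); current strictly decreasing in $\delta$ at 1 V.

One contract deserves its own paragraph: monotonicity of the current in
bias. A single orbital per nucleotide - the minimal surrogate - leaves 14
levels under a ramp that drops 0.4 of the bias at each end; individual level
entries into the Fermi window then compete with bias-induced spectral-weight
loss at the detuned contacts, and the tabulated current shows 6-13%
non-monotone swings. The five-orbital manifold (70 levels, spacing
comparable to the probe broadening) is what makes the I-V smooth; this is
why the shipped fixture is multi-orbital even though single-orbital toys
remain the basis of every closed-form unit test. A small residue survives
at any finite level count: across roughly forty explored configurations the
best-behaved tables still show isolated backward steps of a few percent
above ~0.7 V. The contract therefore asserts strict growth over the
[0, 0.3] V turn-on, tolerates adjacent-bias decreases up to 10% of the
plateau current (the measured class floor is about half that), and requires
the 1 V current to stay within 70% of the plateau maximum; every swept
table records its own worst step in the `monotone_check` attribute. One
consequence worth knowing: where the table has a locally decreasing branch,
a nonlinear network can admit more than one consistent operating point, and
the two Kirchhoff iteration schemes below may settle on slightly different
branches for cells parked in that region. Each scheme is deterministic, and
all conservation checks hold on either branch.

## The crossbar: reference solver and parametric model

A read drives one wordline at $V_\mathrm{in}$ (default 1 V) through an
interconnect segment, leaves the other wordlines floating, and grounds every
bitline at the bottom of its column; every adjacent-cell segment along
wordlines and bitlines has resistance $R_\mathrm{int}$. The reference
solver, `solve_kirchhoff()`, performs full nodal analysis on this ladder
network with two nodes per cell. The default iteration keeps the linear
interconnect network fixed - factorized once per array and cached, with the
driven row's source segment applied as a rank-one update - and re-injects
each cell's table current as a nonlinear nodal source; because cell
conductances (about $10^{-9}$ S) are orders of magnitude below the
interconnect conductance, this contracts rapidly and drives the true
nonlinear KCL residual to machine precision. The classical alternative
(`method = "secant"`), which re-linearizes each cell at its operating point
through the I-V secant and refactorizes each sweep, is kept for
cross-validation; it seeds from the secant at 0.05 V and damps adaptively on
oscillation, and its acceptance threshold scales with the relaxation factor
so a damped step cannot fake convergence. Convergence means the largest
cell-voltage change falls below `tol` (default $10^{-6}$ V); every converged
solve satisfies KCL at every node to $10^{-9} V_\mathrm{in}/R_\mathrm{int}$
and balances source power against dissipated power (cells plus every
interconnect segment) to $10^{-9}$ relative - both are asserted in the
suite, and the nodal solution is checked against an independently assembled
dense netlist.

The fast model replaces the network solve with a closed-form column profile
along the driven wordline scaled by sneak-path factors. For driven row $i$
with cell conductances $G_{ik}$ and segment conductance $g$,

$$V_{ij} = \frac{1 + \sum_{k=j+1}^{n} G_{ik} \sum_{w=j+1}^{k} g^{-1}}
{1 + \sum_{k=1}^{n} G_{ik} \sum_{w=1}^{k} g^{-1}}\; V_\mathrm{in}\,\alpha_i,
\qquad I_{ij} = \beta_j\, I_\mathrm{DNA}(V_{ij}).$$

A note on the denominator: with the empty-sum convention applied to a lower
index of $w = j+1$ in both sums, every $k \le j$ term vanishes and the ratio
collapses to 1, making the profile flat in $j$ - visibly inconsistent with
the column-wise voltage degradation the model is meant to reproduce.
Starting the denominator's inner sum at the first segment ($w = 1$) restores
the expected behaviour and agrees with the exact single-wordline ladder to
first order in $G/g$ (we verified the two-cell case by hand). The package
therefore defaults to the corrected form (`form = "calibrated"`) and keeps
the literal collapsed form available (`form = "literal"`) for comparison.

The factors $\alpha_i$ (row) and $\beta_j$ (column) absorb the interplay of
interconnect resistance and sneak paths. Their published closed forms are
not reproduced in the source material, so `estimate_sneak_parameters()`
defines them operationally: solve the homogeneous linear array at the
average cell conductance $G_\mathrm{avg}$ with the Kirchhoff oracle (one
factorization, rank-one source updates across rows), then set
$\alpha_i = \mathrm{mean}_j\, V^{K}_{ij}/(V_\mathrm{in}\rho_j)$ with
$\rho_j$ the closed-form profile at $G_\mathrm{avg}$, and
$\beta_j = \mathrm{mean}_i\, I^{K}_{ij}/I_\mathrm{cell}(V^{K}_{ij})$.
Both are bias-independent (the calibration network is linear - asserted by
solving at two biases), equal 1 when $R_\mathrm{int}\to 0$, and degrade
toward row 1 and the far column, which is where read distortion peaks.
`iterate_parametric()` then alternates the profile with the conductance
update $G_{ij} = I_\mathrm{DNA}(V_{ij})/V_{ij}$ from a 0.05 V seed; driven
rows are electrically independent in this model, so `readout_map()` iterates
all rows as one matrix fixed point. On homogeneous 64x64 arrays at 10 kOhm
the parametric and Kirchhoff read-out maps agree within 5% RMS (asserted);
the agreement degrades as $R_\mathrm{int}$ approaches the cell resistance,
which is the documented regime limit of the approximation.

`array_power()` reports the mean dissipated power over sequential row reads,
evaluated on the Kirchhoff solution because it needs branch currents; a
parametric state is refused rather than approximated.

## Read-out scoring, Monte Carlo, and the storage benchmark

`optimal_threshold()` scans every realizable decision boundary between
consecutive values of the pooled sorted read currents (plus the two
all-one-class extremes; boundaries between tied values are excluded because
no threshold realizes them), classifies currents at or above the threshold
as logic 1, and returns the boundary minimizing total misclassifications,
breaking ties toward the lower threshold. A brute-force grid scan serves as
its oracle in the suite.

`run_monte_carlo()` models contact-induced Fermi-level variability: each
simulation draws an equiprobable random bit matrix and uniform offsets
$\delta \in [0, \delta_\mathrm{max}]$, shifts each cell's I-V by its offset
(linear interpolation in $\delta$; the tables must bracket
$\delta_\mathrm{max}$), solves the read-out, and scores the per-array
optimal threshold. Offsets default to one draw per memory cell - each
junction is its own single-molecule system - with a per-simulation mode
available. The solver defaults to the parametric model, which is what makes
thousand-simulation studies interactive; the Kirchhoff oracle is a
configuration switch, and read power can be added per simulation on request.
Reproducibility is structural: one master seed draws per-simulation
substream seeds up front, so identical configurations are bit-identical
regardless of execution order. Failed simulations are counted, never
silently dropped.

The storage benchmark (`evaluate_storage()`) loads images - by default
synthetic smoothed random fields whose bit loads concentrate in the
critical 50-70% band while spanning 40-80% (`synthetic_images()`; the
generator rank-flattens each field and shifts it so the fraction of pixels
above mid-gray equals a load drawn from a Beta(2,2) law on [40, 80]) - onto
each array size, reads them back at each interconnect resistance with the
Kirchhoff solver, and tabulates BER by bit load plus the average read power.
How the original benchmark binarized its natural-image dataset is not
stated; `image_to_bits()` defaults to a global median threshold for user
images and pairs the synthetic generator with a fixed mid-gray threshold
that recovers the encoded loads exactly, with nearest-neighbour resizing or
center-cropping for size mismatches - all documented stand-ins.

With the shipped fixtures the regime map reproduces the qualitative device
physics: error-free read-out at 10 kOhm for both 64x64 and 128x128 arrays,
growing error rates and shrinking mean cell voltage through 100 kOhm to
1 MOhm, mean voltage increasing with $\delta_\mathrm{max}$, and read power
lower at 1 MOhm than at 10 kOhm. One departure from a strictly monotone
power law is worth stating plainly: between 10 kOhm and 100 kOhm the
driven wordline's Joule dissipation (which scales like
$I^2 R_\mathrm{int} n^3$) grows faster than the cell currents fall, so
the total read power of 48x48-and-larger arrays passes through a mild
maximum near 100 kOhm before dropping at 1 MOhm. Suppressing that bump
would require cell currents so small that the 1 MOhm regime no longer
produces the error growth above, so the bump is kept and documented as a
property of the surrogate's nanoamp current scale. The suite asserts the trends;
the absolute error percentages and microwatt figures of the original
device depend on its DFT-level I-V curves and are outside what a surrogate
can claim.

## Problem sizes and known limitations

The default test and acceptance runs use 7-base-pair duplexes (70-orbital
surrogates), 2 meV transport grids for table generation, 64x64 and 128x128
arrays, 50-image storage benchmarks, and 100-simulation Monte Carlo runs -
sizes chosen so the whole suite completes in minutes on a single core while
every claim above is exercised at full fidelity.

Limitations to keep in mind: the potential ramp is imposed, not
self-consistent, so contact electrostatics enter only through the 40/20/40
profile; dephasing is elastic (Buettiker probes), with no inelastic or
time-dependent transport; the crossbar is purely resistive - capacitive
transients, and hence latency, are out of scope; floating wordlines are
ideally disconnected; write operations do not exist (the device is a ROM);
and the surrogate fixtures reproduce stated orders of magnitude and trends,
not the quantitative I-V of any real sequence. Passing tests demonstrate
correctness of the transport algebra, the circuit solvers, and the
statistical machinery on fixtures that emulate the device regime - they do
not validate the device concept against experiment.
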