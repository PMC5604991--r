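---
title: "A coupled fluid-structure-electrophysiology model of cochlear micromechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled fluid-structure-electrophysiology model of cochlear micromechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`cortimech` simulates the linearized, frequency-domain mechanics of the
gerbil cochlea as three coupled systems solved simultaneously:

1. **Scala fluids.** Two 2-D rectangular compartments (height H = 0.3 mm
   each) filled with inviscid, incompressible fluid, so the complex
   pressure obeys the Laplace equation. The basal boundary carries the
   oval window (prescribed stapes velocity, 1 nm/ms by default, positive
   into the cochlea) above the partition and the pressure-release round
   window below it; the helicotrema connects the compartments at the
   apical end (pressure equality over the last column plus net-flux
   closure). The bottom compartment couples to the basilar-membrane (BM)
   midline, the top compartment to the tectorial-membrane (TM) edge over
   the hair bundles.

2. **Organ of Corti complex (OCC).** A 3-D Euler-Bernoulli space-frame
   (6 DOF per node) repeated every 10 um: a two-zone BM (arcuate zone
   hinged at the spiral lamina, pectinate zone clamped at the spiral
   ligament), the pillar truss, the merged outer-hair-cell (OHC) axial
   element on its Deiters cell, the reticular lamina (RL), and a
   two-zone TM clamped at the spiral limbus. Adjacent sections are tied
   by longitudinal beams (BM, RL, TM) and by the Deiters phalangeal
   process, which spans one section toward the apex. The hair bundle is
   a radial shear spring (pivot stiffness k_OHB from the parameter
   table) in parallel with the subtectorial shear-film damper
   c_STS = mu L w / h, plus a much stiffer axial strut along the bundle
   height. Viscous losses are stiffness-proportional Rayleigh damping,
   alpha_C(x) = 0.963 exp(0.413 x) us, plus the two discrete damper
   families (c_STS, and the OHC axial damper, 0.3-0.75 uN s/m per cell).

3. **OHC electrophysiology.** Mechano-transduction is a two-state
   gating channel linearized about a resting open probability of 0.4;
   the gating force is the product of the gating swing (0.7 nm) and the
   gating-spring stiffness (6 mN/m), giving dp/dX = z p0 (1-p0) / kT and
   i_MET = G_s,max (E_e - v_m0) dp/dX per metre of bundle shear. The
   membrane potential follows a first-order RC circuit,
   V_m = i_MET / (G_tot + j w C_tot) with G_tot = G_m + G_s,max p0 and
   C_tot = C_m + C_s; the resulting corner frequency runs from roughly
   13 kHz at the basal extreme to 0.16 kHz at the apical extreme, so the
   receptor potential lags the transduction current by approaching a
   quarter cycle at the best frequency. Two active forces act: the
   somatic force f_OHC = g_OHC V_m (0.1 nN/mV per cell,
   contraction-positive, applied as a self-equilibrated axial pair) and
   the bundle reactive force f_MET = f_MET,max dp_open (a
   self-equilibrated pair on the shear DOFs). Three OHC rows are merged
   into one element per section, so merged force gains and stiffnesses
   carry a factor 3 and per-cell quantities are reported after dividing
   by 3. A passive solve zeroes only the force-coupling columns; the
   circuit is still driven and reported.

All quantities use the harmonic convention e^{+j w t}. Power metrics are
cycle averages: the slow-wave flux P_flux(x) = (w/2) Int Re(p_slow
v_f*) dz with p_slow = p - p(L,0) and v_f = -(1/j w rho) dp_slow/dx; the
dissipation P_loss = (1/2) v^H C v; the stapes input power with an
effective stapes width calibrated from the passive identity P_stapes =
P_f2s at 4 kHz and then reused for active runs; and the per-cell somatic
power P_OHC = (1/2) Re(f_OHC v_OHC*).

## Parameters and tonotopy

All geometric, elastic and electrical parameters are anchored at x = 2
and 10 mm (`standard_anchors()`) and interpolated log-linearly
(exponentially in x), the natural law for a cochlea whose characteristic
frequency map is exponential; anchored values are reproduced exactly at
the anchors and the law is continued beyond them. The one sign-changing
parameter, the TM attachment angle theta, interpolates linearly from
+1.5 deg at 2 mm to -3.5 deg at 10 mm, crossing zero near x = 4.4 mm;
this makes the radial TM motion reverse direction there, which is why
the z_TM transfer function has a gain minimum and a 180-degree phase
flip near x = 4 mm. The extrapolated RC corners at the two extremes
bracket 0.2-15 kHz within a factor of two.

## Choices the anatomy does not pin down

Several elements of the cross-section are not determined by the
published parameter table; they were fixed once, on anatomical grounds
and against published operating points for the gerbil cochlea (passive
peak places of 1.2/5.4/9.7 mm for 18.6/4.4/0.78 kHz tones and a stapes
pressure of about 80 mPa), and are never tuned per experiment:

* **Plate shape factors** `s_bm = 4` and `s_tm = 8` multiply the radial
  bending rigidity of the BM and TM. Both membranes are radially
  fibrous composites; a homogeneous thin-beam idealization with the
  tabulated thicknesses underestimates their plate rigidity.
* **Scala width** w(x) = 2 x BM width. The 2-D fluid carries an implied
  radial width; it sets the fluid-structure coupling strength (the
  moving fraction of the partition) and the width used in the power
  integrals.
* **Stereocilia axial strut**, 100 x the pivot-shear stiffness, ties the
  TM underside to the RL transversely: stereocilia are far stiffer
  along their length than in pivot shear. Without it the TM edge
  absorbs the top-compartment pressure locally and no traveling wave
  develops.
* **Outer pillar head** is fused with the RL at the first OHC row,
  giving the RL over the OHCs its transverse support (the tunnel
  triangle).
* **OHC longitudinal tilt** of one section, with the Deiters insertion
  apical of the RL apex, follows the cells' anatomical orientation.
* **Subtectorial gap height** 1 um in c_STS (with the TM body width as
  the film width): the shear film acts across the gap, not across the
  bundle height.
* **Excitatory shear orientation**: bundle deflection of the TM radially
  outward relative to the RL opens channels; with the opposite sign the
  feedback attenuates instead of amplifying.

## Numerics

The coupled system is monolithic: structural DOFs, one membrane
potential per section, and the fluid pressures. Every unknown belongs
to one longitudinal column and all couplings reach at most one column,
so ordering by column yields an exactly block-tridiagonal complex
matrix; a block Thomas sweep with dense LAPACK kernels factors it in
seconds (the full preset has about 130k unknowns). Rows and columns are
max-abs equilibrated before factorization because the structural,
electrical and fluid blocks live on very different scales; every solve
verifies a relative residual below 1e-8. Static probes use a sparse
Cholesky factorization with multiple right-hand sides. Power integrals
use trapezoidal quadrature in z and section sums in x, so energy-balance
tests carry grid-order tolerances. The stiffness-ratio reversal
iterates k <- k_OCC/r_target with fresh probes each round (the
surrounding stiffness decomposes exactly in parallel with the element's
own), converging to a 2-5% profile tolerance in a handful of
iterations.

Presets: `full` (12 mm, 10 um pitch, 1201 sections) for single-frequency
operating points; `coarse` (30 um pitch, 401 sections) for frequency
sweeps, tuning/amplification analyses and the reversal experiments; and
`tiny` (1.2 mm, 50 um pitch, 25 sections) for the test suite, where it
solves in well under a second. The coarse/sweep problem sizes were
chosen so a complete analysis runs in minutes on one core.

## What the model reproduces, and known limitations

With the standard parameter set the model reproduces: the passive
traveling-wave map (peaks at 1.5/4.8/9.0 mm for 18.6/4.4/0.78 kHz,
against published places of 1.2/5.4/9.7 mm); the stapes
pressure (about 97 mPa for 1 nm/ms) and an input impedance of about
120 GPa s/m^3, inside the measured 50-300 range; the basal passive
tuning quality (Q10dB about 1.1); the OHC axial-stiffness ratio between
base and apex (2.3-2.5) and the bundle-stiffness ratio (about 9); the
decrease of the relative OCC stiffness r_OHC toward the apex; the phase
of v_OHC over f_OHC of about 17-20 degrees at the 18.6 kHz peak; the
exact passive power balance; and base-ward amplification that grows
steeply with the somatic gain.

Limitations to keep in mind when reading test output as evidence about
real cochleae:

* The model is linear: no saturating transduction, no level-dependent
  effects.
* The fluid is 2-D and inviscid; all viscous loss is lumped into the
  structural damping.
* The minimal cross-section topology (one node per structure per
  section) makes the active feedback concentrate in a localized
  RL/OHC internal resonance lying a couple of millimetres apical of the
  passive place for the same frequency, rather than pumping the BM
  traveling wave continuously. Location-dependent amplification is
  therefore reproduced toward the base (about 37 dB at x = 3 mm, inside
  the reference 30-50 dB band) but is essentially absent for fixed
  mid-frequency tones (about 0 dB change on doubling g_OHC at 4 kHz,
  apical amplification of a few dB instead of the published 10-20 dB,
  and per-cell peak powers an order of magnitude below published
  estimates of several hundred fW), and the apical passive Q10dB is
  broader than the published 0.9 (the basal 1.1 is matched). Matching those numbers requires
  cross-section detail (multi-node RL and TM, three OHC rows,
  distributed masses) beyond the minimal topology, not different
  physics.
* The standard r_OHB profile is nearly flat along the length, so
  reversing it barely changes the bundle-stiffness end-ratio, unlike
  the order-140 end-ratio that a strongly decreasing profile would
  require for its reversal.
* The gating force is instantaneous (displacement-proportional), so the
  hair-bundle active power P_MET is identically zero per cycle; it is
  computed and reported only to close the active energy balance.
* The fast/slow pressure decomposition subtracts only p(L,0); because
  the two interacting surfaces differ (TM edge above, BM midline
  below), p_slow is not strictly antisymmetric across the partition.

## Reproducibility

Model construction is fully deterministic for a given configuration;
the seed in `model_spec()` exists for optional parameter-jitter
robustness studies and never changes the standard fixtures. Identical
configurations produce bit-identical CSV outputs through
`run_experiment()`.
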