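# kpuu

Estimating the unbound brain-to-unbound plasma partition coefficient
(Kp,uu = Cu,br/Cu,pl) of CNS drug candidates from a **single one-hour
transwell experiment** in an endothelial/glial co-culture model of the
blood-brain barrier — together with the reference unbound-fraction assays
and the concordance statistics used to validate such predictions against
in vivo data.

Only the free (unbound) brain concentration engages CNS targets, and for
many compounds efflux at the blood-brain barrier keeps it far below the
free plasma concentration. Microdialysis measures it directly but does not
scale to screening; the usual surrogates need both an in vivo study and a
separate binding assay per compound. The approach implemented here reads
two ratios out of one in vitro experiment:

- **R_1h** — the receiver/donor concentration ratio at 1 h, a non-steady-state
  estimate of Cu,br/Cu,pl;
- **R_ss** — a steady-state extrapolation: the donor decline gives an influx
  clearance `CL_in = λ·V_lum` with `λ = log(C_d0/C_d,t)/t`; with the donor
  forced to that exponential, the receiver is fitted as an open compartment
  with exit clearance `CL_out = µ·V_ab` (lumping backflux with glial binding
  uptake), and `R_ss = CL_in/CL_out` is the plateau under a constant donor,
  mirroring the in vivo constant-rate-infusion steady state.

The package also provides the exact closed-form forward simulator of the
two-compartment transwell system, sucrose-tracer integrity QC, fraction
unbound in plasma/brain homogenate/brain slice (with dilution and
water-adhesion corrections), in vivo ratio translation
(`Cu,br/Cu,pl = (C_br/C_pl)·(fu,br/fu,pl)` after residual-blood
correction), free-brain profile prediction, microdialysis carrier-flow
correction, fold-agreement and r² concordance statistics, a packaged
92-compound validation dataset, and a seeded synthetic-data generator.
A thin command-line interface is installed at
`system.file("cli", "kpuu.R", package = "kpuu")`.

## Worked example

Fit the steady-state extrapolation to a one-hour measurement (donor 2 µM
falling to 1.6 µM, receiver rising to 0.2 µM):

```r
library(kpuu)
m <- transwell_measurement(C_d0 = 2, C_d_t = 1.6, C_r_t = 0.2, t = 60)
fit <- transwell_fit(m, transwell_geometry(V_lum = 1500, V_ab = 2500))
summary(fit)
#> Fitted kinetic constants:
#>   lambda_donor  0.003719 1/min   CL_in  5.579 uL/min
#>   mu_receiver   0.006035 1/min   CL_out 15.09 uL/min
#> Unbound brain/plasma ratio estimates:
#>   R_1h = 0.125, R_ss = 0.3697
```

The compound's 1-h ratio is 0.125, but the extrapolated steady-state
ratio is 0.37: transfer had not equilibrated at 1 h, so the single-timepoint
ratio alone would understate brain exposure threefold.

Concordance of in vitro predictions with in vivo values over the packaged
30-drug table:

```r
concordance_report(kpuu_table2(),
  list(invitro_vs_slice = c("invitro_ss", "invivo_slice")), k = 2)
#> invitro_vs_slice (invitro_ss vs invivo_slice, n = 30)
#>   r2 = 0.6672
#>   Within 2-fold: 26 of 30 pairs (87%); 4 beyond
#>   discordant: Baclofen, Fexofenadine, Morphine, Risperidone
```

Dose selection from an in vitro potency: with a steady-state ratio of 0.15
and steady-state free plasma levels of 40/400/3300 nM at three doses,

```r
efficacy_coverage(R_ss = 0.15, Cu_pl_per_dose = c(40, 400, 3300),
                  IC50 = 55, doses = c(30, 100, 300))
#>  dose Cu_pl Cu_br_pred coverage effect_anticipated
#>    30    40          6    0.109              FALSE
#>   100   400         60    1.091               TRUE
#>   300  3300        495    9.000               TRUE
```

predicted free brain levels of 6, 60 and 495 nM cover the 55 nM IC50 only
at the two higher doses — i.e. a pharmacological response is anticipated
there and not at the lowest dose.

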