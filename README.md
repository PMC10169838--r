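# ternarybinding

Mass-action modelling of ternary complex formation for **universal adaptor
receptors** — engineered T cell receptors (adaptor CARs, adaptor synNotch)
whose antigen specificity is supplied at run time by a tag-conjugated
antibody that bridges the receptor to a tumor antigen. Receptor signalling
is proxied by the concentration of the three-body complex
*T cell receptor · antibody · antigen*, and the package exists to answer
dosing questions about it: where the activation peak sits, how wide the
effective dose window is, and why excess antibody shuts signalling down
(the **hook/prozone effect**).

Intended users: systems-biology and immuno-engineering groups analysing
adaptor-receptor titration data or designing adaptor dosing.

## Model

Six species — free receptor `Tc`, antibody `Ab`, antigen `Tu`, binary
complexes `Tc.Ab` and `Ab.Tu`, ternary `Tc.Ab.Tu` — coupled by four
reversible mass-action reactions (forward rates k<sub>f1..f4</sub> in
nM⁻¹s⁻¹, reverse k<sub>r1..r4</sub> in s⁻¹, K<sub>Di</sub> =
k<sub>ri</sub>/k<sub>fi</sub>):

    Tc + Ab     ⇌  Tc.Ab        (kf1, kr1)
    Ab + Tu     ⇌  Ab.Tu        (kf2, kr2)
    Tc.Ab + Tu  ⇌  Tc.Ab.Tu     (kf3, kr3)
    Tc + Ab.Tu  ⇌  Tc.Ab.Tu     (kf4, kr4)

The resulting six ODEs (e.g. d[Tc]/dt = −rxn₁+rxn₂−rxn₇+rxn₈) are solved
with a compiled L-stable Rosenbrock integrator; equilibria are
cross-checked against an independent Newton root-finder on the conserved
totals. On top of this sit hook-effect metrics, bounded least-squares
fitting of the eight rates to arbitrary-unit activation readouts (MFI),
900-simulation parameter scans, and a seeded synthetic data generator.

## Worked example

```r
library(ternarybinding)

params <- literature_params("FMC63_synNotch")  # synthetic stand-in rates
setup  <- experiment_setup()                   # 1e5 + 2e5 cells in 0.2 mL
curve  <- equilibrium_dose_response(setup, params)
hook_metrics(curve)
```

```
Hook metrics: peak 0.003345 nM at 0.07609 ug/mL; 50% window [0.01314, 0.4406] ug/mL; hook detected
```

Reading: ternary complex formation (and hence receptor signalling) is
maximal at ~0.08 µg/mL antibody — the same order as the experimentally
observed 0.25 µg/mL optimum for this antibody/receptor pair — holds at
least half-maximum between ~0.013 and ~0.44 µg/mL, and collapses at high
dose (by 10 µg/mL the curve is below 4% of peak): the hook effect, caused
by excess antibody saturating receptor and antigen pools separately.

Fitting observed readouts and scanning parameters:

```r
specs <- default_synthetic_specs(seed = 1)            # 4 antibodies x 2 receptors
bundle <- generate_dataset(specs, "scratch/demo")     # observed.csv etc.
obs    <- read_observed_csv(bundle$paths[["observed"]])
fit    <- fit_cohort(obs, lapply(specs, `[[`, "params"),
                     lapply(specs, `[[`, "setup"))

scan <- scan_parameter("kf1", c(1e-6, 1e-1), params, setup)  # 900 simulations
plateau_threshold(scan)   # on-rate beyond which ternary formation saturates
```

A command-line pipeline wrapping the same stages (subcommands `simulate`,
`dose-response`, `fit`, `scan`, `synth`) is installed at
`system.file("cli", "ternarybinding", package = "ternarybinding")`.

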