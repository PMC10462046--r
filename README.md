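# scramblekit

Lipid **scramblases** let phospholipids cross between the two leaflets of a
membrane bilayer without ATP, typically along a membrane-spanning
hydrophilic groove ("credit-card" mechanism: the headgroup slides along the
groove while the acyl tails stay in the hydrophobic core). In molecular
simulations, scrambling activity is established by three quantitative
analyses: counting flip-flop events in unbiased trajectories, mapping
lipid-phosphate and water densities around the protein, and computing the
free-energy profile of flip-flop along a collective variable — the barrier
reduction relative to a protein-free bilayer is the headline number
(e.g. a drop from 62 to 7 kJ/mol, an ~89% reduction, in coarse-grained
simulations of the insertase MTCH2-class systems this package targets).

scramblekit implements that analysis chain as a tested R package for people
who run membrane simulations (or consume their outputs) and want the
scrambling numbers reproducibly:

- **Leaflet assignment & event counting** — per-snapshot membrane center
  from phosphate positions (periodic-boundary safe), instantaneous
  scrambled-lipid counts with a 200 ns running average, cumulative
  transition events, and rates in events/μs with bootstrap CIs.
- **Flip-flop collective variable** — signed z-distance between a lipid
  phosphate and the local membrane center of mass inside a cylinder
  (R = 2.0 nm plain / 3.0 nm protein systems), plus harmonic umbrella and
  flat-bottom restraint energies (d0 = 2.5 nm, k = 500 kJ mol⁻¹ nm⁻²).
- **Umbrella bookkeeping & WHAM** — window placement on pulling traces,
  equilibration discards, and a WHAM solver
  `P(b) = Σᵢnᵢ(b) / Σᵢ Nᵢ exp[(fᵢ − Uᵢ(ξᵦ))/k_BT]` solved via its convex
  likelihood + fixed-point polish, with min-zero profiles, asymmetry error
  bars and barrier/reduction reports.
- **Protein-centered maps** — Kabsch superposition (proper rotations only),
  RMSD series on separate fit/report selections, voxel number densities
  with exact count conservation, OpenDX export.
- **Synthetic membrane generator** — overdamped Langevin lipids in a
  quartic double-well (optional low-barrier "groove" with gate bump),
  planted-event fixtures and exact Boltzmann umbrella samples, so the whole
  pipeline is validated against known ground truth.

Structures are read from GRO/PDB; trajectories use a documented plain-text
container (no binary XTC/TRR reader is bundled). Units: nm, ns, kJ/mol, K;
membrane normal +z.

## Worked example

The `analysis/` scripts run the full study on the synthetic scenarios
(plain 290-lipid bilayer with a 62 kJ/mol flip-flop barrier vs a bilayer
with a 7 kJ/mol groove pathway):

```sh
Rscript analysis/01_simulate.R      # generate trajectories -> results/
Rscript analysis/02_scrambling.R    # traces + rates
Rscript analysis/03_free_energy.R   # umbrella windows + WHAM
Rscript analysis/04_density_rmsd.R  # aligned density map + RMSD series
```

Output from a run of stages 2 and 3:

```
proteinless  events    0  rate   0.00 events/us  (95% CI 0.00-0.00)
groove       events   11  rate   5.50 events/us  (95% CI 3.00-8.53)
barrier scan (events over 2 us, 100 lipids):
 barrier_kJmol events rate_per_us
             5   1514         757
            10    408         204
            20     20          10

proteinless barrier:  62.16 kJ/mol (asymmetry error 0.13)
groove barrier:        6.99 kJ/mol (asymmetry error 0.21)
barrier reduction:    88.7%
```

Read: the high-barrier bilayer shows **zero** scrambling over 2 μs (as a
protein-free membrane should on this timescale), the groove scenario
scrambles at ~5 events/μs, flip rates fall steeply with barrier height
(Kramers behaviour), and WHAM recovers both generator barriers —
62.16 vs 62 and 6.99 vs 7 kJ/mol — giving the 88.7% reduction that a
62 → 7 kJ/mol pair implies. Stage 4 then shows midplane phosphate density
only inside the groove (0.0056 nm⁻³ vs 0.0000 in the surrounding ring):
the density-map analogue of a scrambling pathway.

Programmatic use mirrors the scripts:

```r
library(scramblekit)
sc <- membrane_scenario("demo", n_lipids = 64,
        potential = flipflop_potential(20), duration = 500, seed = 42)
traj  <- simulate_unbiased(sc)
trace <- scrambling_trace(traj, interval = 10, smoothing_window = 200)
scrambling_rate(trace)
```

or config-driven via `run_pipeline(system.file("extdata",
"synthetic-demo.yaml", package = "scramblekit"))`, which writes a manifest
with the effective config, its MD5, the seed and every output file.

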