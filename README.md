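# hippoflow

Simulation and analysis of synapse loss in a hippocampal DG–CA3–CA1
microcircuit.

Early Alzheimer's-like degeneration preferentially destroys the synapses
that layer II of the entorhinal cortex (EC2) makes on the dentate gyrus and
CA3.  `hippoflow` models the consequences in a small but complete
trisynaptic circuit: 21 compartmental neurons (granule, pyramidal, basket,
O-LM and mossy cells, 16 passive compartments each) wired as
EC2 → DG → CA3 → CA1 with perforant-path, mossy-fiber, Schaffer, local
inhibitory and temporoammonic (EC3) pathways, driven by theta-nested
gamma-patterned Poisson input and theta-locked septal disinhibition, with
AMPA/NMDA/GABA-A receptor kinetics and a potentiation-only (LTP) learning
rule.  Degeneration is modelled as staged, cumulative inactivation of EC2
synapses at 9%, 18%, 26% and 35%, and each stage is compared with the
intact control.

The package is aimed at computational neuroscientists who want a desk-scale,
fully reproducible test bed for how progressive denervation reshapes

* **burst firing** — number of spikes, spikes per burst, burst duration and
  inter-burst interval (IBI), per cell and per region;
* **dynamical complexity** — delay-embedding reconstruction with AMI delay
  and false-nearest-neighbour dimension selection, Grassberger–Procaccia
  correlation dimension *D₂* (slope of log *C(r)* vs log *r* over an
  automatically selected scaling region), recurrence-plot Shannon entropy
  (diagonal-line-length histogram, bits), and the maximal Lyapunov exponent
  λ by Rosenstein's method (slope of the mean log nearest-neighbour
  divergence);
* **directed information flow** — plug-in Shannon entropy *H*, mutual
  information *I(X;Y)* and Schreiber transfer entropy
  *TE(X→Y) = I(Y_{t+1}; X_t | Y_t)* on binned multiunit spike counts, with
  pathology values expressed as percent of the same-seed control.

Every estimator ships with synthetic benchmarks of known properties
(logistic and Hénon maps, the Lorenz system, exactly solvable coupled
binary processes, theta-nested Poisson trains) so the whole analysis stack
is validated without any external data.

## A worked example

```r
library(hippoflow)

cfg <- build_default_network(seed = 1, duration = 4000)
sim <- integrate_network(cfg)
sim
#> <simulation_result> 21 cells, 4000 ms at dt = 0.1 ms
#>   total spikes: 4442

print(simulation_burst_stats(sim)$per_region, digits = 3)
#>       region n_spikes spikes_per_burst burst_duration inter_burst_interval
#> 1         DG      165             5.16           29.2                 94.8
#> 2        CA3      243             7.53           45.9                 77.4
#> 3        CA1      295             9.22           57.6                 66.2
#> 4    CA3-CA1      269             8.37           51.7                 71.8
#> 5 DG-CA3-CA1      234             7.30           44.2                 79.5

round(simulation_infoflow(sim)$te, 3)
#>  DG->CA3  CA3->DG CA3->CA1 CA1->CA3
#>    0.143    0.042    0.459    0.116
```

The control circuit bursts once per 8 Hz theta cycle: burst duration plus
IBI sums to roughly one 125 ms cycle in every region, and transfer entropy
is larger along the anatomical DG→CA3 and CA3→CA1 directions than against
them.  Applying the degeneration model is one call:

```r
del <- apply_deletion(cfg, 0.35, deletion_schedule())
sum(!del$synapses$active)   # 14 of the 40 EC2 synapses inactivated
```

The full study design — control plus four deletion stages, replicated over
seeds, with burst, complexity and information-flow metrics in one tidy
table — is run by the pipeline:

```r
tab <- run_experiment(experiment_spec(n_seeds = 10))
summarize_trends(tab)
```

Under the shipped defaults the region spike count, spikes per burst and
burst duration fall monotonically with deletion level while the IBI rises,
and the multiunit Lyapunov exponent of CA3–CA1 flips from non-positive
(control) to positive at every deletion stage — the degeneration drives the
circuit from a stereotyped theta limit cycle towards irregular,
divergence-prone dynamics.

A thin command-line front end with verbs `build-config`, `simulate`,
`analyze`, `run-all` and `benchmarks` is installed at
`inst/cli/hippoflow.R`.

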