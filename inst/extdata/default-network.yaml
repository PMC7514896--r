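# Default quantitative parameters of the 21-cell DG-CA3-CA1 microcircuit.
# The wiring diagram (which cell contacts which, and on which compartment)
# is structural and lives in code; every tunable number lives here.
# Units: capacitance uF/cm^2, conductances mS/cm^2, voltages mV, times ms,
# rates spikes/s, frequencies Hz, phases radians.
schema_version: "1.0"
dt: 0.1
duration: 16000
mg_mM: 1.0

cells:
  granule:   {cm: 1.0, gl: 0.10, el: -65.0, ga: 8.0, threshold: -57.0, reset: -67.0, refractory: 7.0}
  pyramidal: {cm: 1.0, gl: 0.10, el: -65.0, ga: 8.0, threshold: -57.0, reset: -67.0, refractory: 7.0}
  mossy:     {cm: 1.0, gl: 0.10, el: -65.0, ga: 8.0, threshold: -57.0, reset: -67.0, refractory: 7.0}
  basket:    {cm: 1.0, gl: 0.10, el: -65.0, ga: 8.0, threshold: -56.0, reset: -65.0, refractory: 4.0}
  olm:       {cm: 1.0, gl: 0.05, el: -65.0, ga: 8.0, threshold: -54.0, reset: -65.0, refractory: 8.0}

receptors:
  AMPA:   {tau_rise: 0.5, tau_decay: 3.0,  reversal: 0.0}
  NMDA:   {tau_rise: 3.0, tau_decay: 80.0, reversal: 0.0}
  GABA_A: {tau_rise: 0.5, tau_decay: 7.0,  reversal: -75.0}

# External drives.  EC2 and EC3 are theta-modulated, gamma-carried Poisson
# sources, one independent train per synaptic contact; their theta phases
# differ by pi so strong EC2 input coincides with weak EC3 input.  The septal
# source is a deterministic theta-locked GABAergic burst onto interneurons.
drives:
  EC2:    {theta_frequency: 8.0, gamma_frequency: 40.0, theta_phase_offset: 0.0,
           mean_rate: 120.0, theta_depth: 1.0, gamma_depth: 0.5, seed_offset: 101}
  EC3:    {theta_frequency: 8.0, gamma_frequency: 40.0, theta_phase_offset: 3.14159265358979,
           mean_rate: 90.0, theta_depth: 1.0, gamma_depth: 0.5, seed_offset: 202}
  septum: {theta_frequency: 8.0, theta_phase_offset: 0.0, spikes_per_cycle: 4,
           intra_burst_isi: 3.0, seed_offset: 0}

# Per-pathway synapse parameters.  `gmax` is the AMPA peak conductance; when
# `nmda_ratio` > 0 each contact carries an NMDA twin at the same compartment
# with peak conductance `gmax * nmda_ratio`.  EC2 contacts are AMPA-only so
# the degeneration model removes identical drive quanta.
pathways:
  EC2_to_DG_granule:    {gmax: 0.1227, nmda_ratio: 0.0, weight: 1.0, delay: 2.0, plastic: true}
  EC2_to_DG_basket:     {gmax: 0.023, nmda_ratio: 0.0, weight: 1.0, delay: 2.0, plastic: false}
  EC2_to_CA3_pyramidal: {gmax: 0.115, nmda_ratio: 0.0, weight: 1.0, delay: 2.0, plastic: true}
  EC2_to_CA3_basket:    {gmax: 0.023, nmda_ratio: 0.0, weight: 1.0, delay: 2.0, plastic: false}
  EC3_to_CA1:           {gmax: 0.1725, nmda_ratio: 0.15, weight: 1.0, delay: 2.0, plastic: true}
  mossy_fiber:          {gmax: 0.80, nmda_ratio: 0.15, weight: 1.0, delay: 1.5, plastic: true}
  mossy_cell_feedback:  {gmax: 0.30, nmda_ratio: 0.15, weight: 1.0, delay: 1.5, plastic: false}
  schaffer:             {gmax: 0.50, nmda_ratio: 0.15, weight: 1.0, delay: 2.0, plastic: true}
  local_excitation:     {gmax: 0.10, nmda_ratio: 0.5, weight: 1.0, delay: 1.0, plastic: false}
  local_inhibition:     {gmax: 1.60, nmda_ratio: 0.0, weight: 1.0, delay: 1.0, plastic: false}
  septal:               {gmax: 0.60, nmda_ratio: 0.0, weight: 1.0, delay: 1.0, plastic: false}

ltp: {learning_rate: 0.0005, weight_ceiling: 1.15, coincidence_window: 20.0}
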