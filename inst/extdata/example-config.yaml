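# Example run configuration for runPipeline(): simulate a 10-minute
# sweep-protocol recording of a caged tetravalent target plus a fast
# non-target background species behind an entropic gate, then detect
# events and profile the caged levels.
seed: 1
filter_hz: 500
output_dir: porecage-out
analyses: [caging, kinetics]
simulation:
  sampling_rate_hz: 5000
  conductance_nS: 1.94          # 1.9* pore class
  noise_sd_pA: 2
  protocol:
    mode: sweeps
    total_s: 600
    flip_mV: 100
    flip_s: 0.2
    measure_mV: -75
    measure_s: 2
  species:
    - name: SA
      concentration_nM: 25
      k_on_per_uM_s: 8.77
      occupancy:                # caged: multivalent occupancy model
        n_sites: 4
        n_tags: 10
        k_bind: 0.12
        k_unbind: 1.0
        k_escape: 0.2           # trans-side competitor raises escape
        depth_max_pct: 48.0
        depth_min_pct: 32.6
    - name: BT
      concentration_nM: 100
      k_on_per_uM_s: 2.0
      dwell_mean_s: 0.05        # non-caged square blockades
      depth_pct: 75.9
      depth_jitter_sd: 2
  gate_attenuation:
    BT: 0.25                    # entropic gate: 4-fold reduced capture
detector:
  open_fraction: 0.90
  close_fraction: 0.95
caging:
  window_s: 60
  bin_pA: 0.1
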