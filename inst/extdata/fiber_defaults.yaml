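# Default generator parameters for synthetic pruriception cohorts.
# Net-AP targets are rounded from the reported QC/SC population cell means;
# response probabilities follow the reported responder fractions.
heat:
  QC:
    burst_rate_hz: 150        # discharge rate during the temperature rise
    plateau_init_hz: 80       # rate at plateau onset, then exponential adaptation
    adapt_tau_s: 0.35
  SC:
    peak_rate_hz: 55          # Gaussian rate bump peaking in the plateau
    peak_time_in_plateau_s: 1.5
    peak_sd_s: 0.6
latency_range_s: [0.1, 0.5]   # minimal conduction latency from skin (C-fiber)
pruritogens:
  QC:
    ALA:     {response_prob: 0.93, target_net_aps: 83, decay_tau_s: 75}
    BAM8_22: {response_prob: 0.72, target_net_aps: 52, decay_tau_s: 75}
  SC:
    ALA:     {response_prob: 0.23, target_net_aps: 10, decay_tau_s: 40}
    BAM8_22: {response_prob: 0.94, target_net_aps: 94, decay_tau_s: 50}
  C_MIA:
    ALA:     {response_prob: 0.00, target_net_aps: 0,   decay_tau_s: 60}
    BAM8_22: {response_prob: 0.33, target_net_aps: 134, decay_tau_s: 60}
  A_MSA:
    ALA:     {response_prob: 0.06, target_net_aps: 14,  decay_tau_s: 60}
    BAM8_22: {response_prob: 0.06, target_net_aps: 129, decay_tau_s: 10}
  A_MIA:
    ALA:     {response_prob: 0.00, target_net_aps: 0, decay_tau_s: 60}
    BAM8_22: {response_prob: 0.00, target_net_aps: 0, decay_tau_s: 60}
vehicles:
  ALA: ECF
  BAM8_22: BAM8_18
  HIS: SALINE
ratings:
  qualities: [itch, pricking_stinging, burning]
  perceive_prob: {itch: 1.0, pricking_stinging: 0.97, burning: 0.93}
  subject_gain_sdlog: 0.5
  quality_gain_sdlog: 0.6
  noise_sdlog: 0.25           # multiplicative (ratio-scale) rater noise
  noise_ar1: 0.85             # smooth drift between successive 30-s reports
  rise_min: 0.7
  zero_floor: 1.0             # ratings below "barely detectable" report as zero
  # decay constants chosen so sensations vanish ~10 min after the MRGPR
  # agonists and ~20 min after histamine-containing stimuli
  stimuli:
    ALA:         {peak: {itch: 22, pricking_stinging: 16, burning: 8}, decay_min: 3.2}
    BAM:         {peak: {itch: 18, pricking_stinging: 14, burning: 7}, decay_min: 3.0}
    HIS:         {peak: {itch: 24, pricking_stinging: 12, burning: 9}, decay_min: 6.3}
    BAM+ALA:     {peak: {itch: 21, pricking_stinging: 15, burning: 8}, decay_min: 3.5}
    BAM+ALA+HIS: {peak: {itch: 23, pricking_stinging: 14, burning: 9}, decay_min: 4.5}
areas:
  measures:
    alloknesis:   {base_cm2: 6,   his_mult: 3}
    hyperalgesia: {base_cm2: 10,  his_mult: 3}
    hyperknesis:  {base_cm2: 8,   his_mult: 3}
    wheal:        {base_cm2: 1.2, his_mult: 4}
    flare:        {base_cm2: 6,   his_mult: 5}
  his_stimuli: [HIS, BAM+ALA+HIS]
  subject_sdlog: 0.4
  noise_sdlog: 0.3
ish:
  human:
    panel: [MRGPRD, MRGPRX1, TRPV1]
    joint:
      MRGPRD+MRGPRX1+TRPV1: 0.140
      MRGPRD+MRGPRX1: 0.0
      MRGPRD+TRPV1: 0.009
      MRGPRX1+TRPV1: 0.009
      MRGPRD: 0.005
      MRGPRX1: 0.0
      TRPV1: 0.285
      none: 0.552
    puncta:
      positive: {mu: 30, size: 8}
      negative: {mu: 0.6, size: 0.8}
  macaque:
    panel: [MRGPRD, MRGPRX1]
    joint:
      MRGPRD+MRGPRX1: 0.100
      MRGPRD: 0.028
      MRGPRX1: 0.075
      none: 0.797
    puncta:
      positive: {mu: 20, size: 8}
      negative: {mu: 0.4, size: 0.8}
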