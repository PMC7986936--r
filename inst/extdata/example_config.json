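{
  "n_hd": 8,
  "n_control": 8,
  "visit_count_law": {
    "3": 0.14,
    "4": 0.14,
    "5": 0.07,
    "6": 0.04,
    "7": 0.61
  },
  "control_visit_count_law": {
    "3": 0.1,
    "4": 0.11,
    "5": 0.08,
    "6": 0.037,
    "7": 0.673
  },
  "time_window": [-6, 5],
  "true_decay": {
    "hd": {
      "precentral": 0.003,
      "superior_frontal": 0.003,
      "middle_frontal": 0.003,
      "inferior_frontal": 0.003,
      "orbital_gyrus": 0.003,
      "supplementary_motor": 0.003,
      "cingulate": 0.003,
      "parahippocampal": 0.003,
      "entorhinal": 0.003,
      "superior_temporal": 0.003,
      "middle_temporal": 0.003,
      "inferior_temporal": 0.003,
      "temporal_pole": 0.003,
      "planum_temporale": 0.003,
      "fusiform": 0.003,
      "postcentral": 0.006,
      "superior_parietal": 0.006,
      "supramarginal": 0.006,
      "angular": 0.006,
      "precuneus": 0.006,
      "calcarine": 0.008,
      "cuneus": 0.008,
      "lingual": 0.008,
      "middle_occipital": 0.008,
      "occipital_pole": 0.008,
      "caudate": 0.0150536303023486,
      "putamen": 0.0186984629811414,
      "white_matter": 0.005
    },
    "control": {
      "precentral": 0.00100503358535015,
      "superior_frontal": 0.00100503358535015,
      "middle_frontal": 0.00100503358535015,
      "inferior_frontal": 0.00100503358535015,
      "orbital_gyrus": 0.00100503358535015,
      "supplementary_motor": 0.00100503358535015,
      "cingulate": 0.00100503358535015,
      "parahippocampal": 0.00100503358535015,
      "entorhinal": 0.00100503358535015,
      "superior_temporal": 0.00100503358535015,
      "middle_temporal": 0.00100503358535015,
      "inferior_temporal": 0.00100503358535015,
      "temporal_pole": 0.00100503358535015,
      "planum_temporale": 0.00100503358535015,
      "fusiform": 0.00100503358535015,
      "postcentral": 0.00100503358535015,
      "superior_parietal": 0.00100503358535015,
      "supramarginal": 0.00100503358535015,
      "angular": 0.00100503358535015,
      "precuneus": 0.00100503358535015,
      "calcarine": 0.00100503358535015,
      "cuneus": 0.00100503358535015,
      "lingual": 0.00100503358535015,
      "middle_occipital": 0.00100503358535015,
      "occipital_pole": 0.00100503358535015,
      "caudate": 0.00100503358535015,
      "putamen": 0.00100503358535015,
      "white_matter": 0.00100503358535015
    }
  },
  "group_offset": {
    "precentral": -2,
    "superior_frontal": -2,
    "middle_frontal": -2,
    "inferior_frontal": -2,
    "orbital_gyrus": -2,
    "supplementary_motor": -2,
    "cingulate": -2,
    "parahippocampal": -2,
    "entorhinal": -2,
    "superior_temporal": -2,
    "middle_temporal": -2,
    "inferior_temporal": -2,
    "temporal_pole": -2,
    "planum_temporale": -2,
    "fusiform": -2,
    "postcentral": -3,
    "superior_parietal": -3,
    "supramarginal": -3,
    "angular": -3,
    "precuneus": -3,
    "calcarine": -3,
    "cuneus": -3,
    "lingual": -3,
    "middle_occipital": -3,
    "occipital_pole": -3,
    "caudate": -7,
    "putamen": -8,
    "white_matter": -2
  },
  "cag_slope": {
    "precentral": 0,
    "superior_frontal": 0,
    "middle_frontal": 0,
    "inferior_frontal": 0,
    "orbital_gyrus": 0,
    "supplementary_motor": 0,
    "cingulate": 0,
    "parahippocampal": 0,
    "entorhinal": 0,
    "superior_temporal": 0,
    "middle_temporal": 0,
    "inferior_temporal": 0,
    "temporal_pole": 0,
    "planum_temporale": 0,
    "fusiform": 0,
    "postcentral": 0.0007,
    "superior_parietal": 0.0007,
    "supramarginal": 0.0007,
    "angular": 0.0007,
    "precuneus": 0.0007,
    "calcarine": 0.001,
    "cuneus": 0.001,
    "lingual": 0.001,
    "middle_occipital": 0.001,
    "occipital_pole": 0.001,
    "caudate": 0.001,
    "putamen": 0.0012,
    "white_matter": 0
  },
  "cag_law": {
    "39": 0.0603947152896591,
    "40": 0.0827254498187322,
    "41": 0.104175701400711,
    "42": 0.120609447902099,
    "43": 0.128376090824164,
    "44": 0.125624695549171,
    "45": 0.113019637006731,
    "46": 0.0934804022912838,
    "47": 0.0710844489171272,
    "48": 0.0496953090221902,
    "49": 0.0319405345017863,
    "50": 0.0188735674763461
  },
  "cag_onset_corr": -0.85,
  "age_mean": 44.59,
  "age_sd": 9.28,
  "age_range": [28, 66],
  "noise_sd": 1,
  "behavior": true,
  "behavior_targets": {
    "tms": 57.8,
    "sdmt": 16.78
  },
  "behavior_baseline": {
    "tms": 20,
    "sdmt": 35
  },
  "behavior_noise_sd": 5,
  "dynamics_form": "dynamic",
  "site_levels": ["Leiden", "London", "Paris", "Vancouver"],
  "site_probs_hd": [0.449, 0.204, 0.204, 0.143],
  "site_probs_control": [0.286, 0.204, 0.286, 0.224],
  "female_p_hd": 0.551,
  "female_p_control": 0.61,
  "tiv_mean": 1420,
  "tiv_sd": 120,
  "tiv_male_shift": 110,
  "seed": 11
}
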