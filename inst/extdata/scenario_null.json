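{
  "design": {
    "initial_snr_db": 7,
    "step_db": 2,
    "n_levels": 5,
    "words_per_level": 10,
    "syllables_per_word": 2,
    "presentation_level_db_hl": 60
  },
  "control": {
    "n_participants": 33,
    "threshold_mean_db": 0.1,
    "threshold_sd_db": 0.45,
    "slope_db": 1.4,
    "within_word_dependence": 0.3,
    "ear_offset_db": -0.2,
    "label": "control"
  },
  "apd": {
    "n_participants": 22,
    "threshold_mean_db": 0.1,
    "threshold_sd_db": 0.45,
    "slope_db": 1.4,
    "within_word_dependence": 0.3,
    "ear_offset_db": -0.2,
    "label": "APD"
  },
  "seed": 1
}
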