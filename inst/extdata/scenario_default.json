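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
    "threshold_mean_db": -0.397749780819861,
    "threshold_sd_db": 0.3,
    "slope_db": 1.4,
    "within_word_dependence": 0.0732577411857116,
    "ear_offset_db": -0.479885171466326,
    "label": "control"
  },
  "apd": {
    "n_participants": 22,
    "threshold_mean_db": -0.021989859851504,
    "threshold_sd_db": 0.6,
    "slope_db": 1.4,
    "within_word_dependence": 0.0655141117404522,
    "ear_offset_db": 0.111599663959948,
    "label": "APD"
  },
  "seed": 1203
}
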