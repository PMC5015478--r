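{
  "seed": 1,
  "n_subjects": 22,
  "mode": "rubberband",
  "isis": [1.5, 3.0, 4.5, 6.0],
  "n_blocks_per_isi": 2,
  "n_stimuli": 150,
  "deviant_prob": 0.2,
  "min_sep": 2,
  "n_lead": 5,
  "alpha_strict": 0.05,
  "alpha_combined": 0.1,
  "noise": { "sd": 8, "pink": 0 },
  "synthesis": "trials"
}
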