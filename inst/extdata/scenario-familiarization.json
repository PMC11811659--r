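{
  "id": "familiarization",
  "label": "quiet residential area, no accident",
  "declared_counts": {
    "green": 0,
    "yellow": 0,
    "red": 0,
    "black": 0
  },
  "mean_duration_min": 5.78,
  "sd_duration_min": 1.71,
  "roster": [],
  "aois": []
}
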