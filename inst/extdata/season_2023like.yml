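# Synthetic season spec emulating the calibration year's 312.8 mm total.
kind: season
spec:
  planting: "2023-05-10"
  season_length: 135
  latitude: 43.35
  elevation: 290
  target_rain_mm: 312.8
  seed: 2023
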