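# Montcalm experimental-site soil: three sampled sandy-loam layers,
# bottom layer extended so the profile covers the maximum root depth.
kind: soil
depth_m: 0.60
compartment_m: 0.05
tau: 0.5
layers:
  - {top_m: 0.00, bottom_m: 0.15, texture: sandy loam, bulk_density: 1.471}
  - {top_m: 0.15, bottom_m: 0.30, texture: sandy loam, bulk_density: 1.255}
  - {top_m: 0.30, bottom_m: 0.45, texture: sandy loam, bulk_density: 1.369}
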