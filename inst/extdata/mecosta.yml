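# Mecosta commercial-farm soil: three sampled loamy-sand layers.
kind: soil
depth_m: 0.60
compartment_m: 0.05
tau: 0.5
layers:
  - {top_m: 0.00, bottom_m: 0.15, texture: loamy sand, bulk_density: 1.564}
  - {top_m: 0.15, bottom_m: 0.30, texture: loamy sand, bulk_density: 1.578}
  - {top_m: 0.30, bottom_m: 0.45, texture: loamy sand, bulk_density: 1.600}
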