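# The canonical conflict scenery: an ambiguous narrow cue pair (North and
# South) plus a broad unambiguous cue due East; the green channel is
# declared but carries no cue.
name: conflict
n_dirs: 120
features: [red, green, blue]
cues:
- feature: red
  profile: bimodal
  centers: [90.0, -90.0]
  kappa: 10.0
- feature: blue
  profile: broad
  centers: 0.0
  kappa: 20.0
  width: 90.0
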