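# Example run configuration: small block with a shallow circular nodule.
# Units are fixed package-wide: mm, N, MPa.
units:
  length: mm
  force: "N"     # quoted: bare N is YAML shorthand for false
  pressure: MPa
domain:
  width: 60
  height: 40
  mesh_size: 8
materials:
  healthy:
    model: ogden
    mu: [0.02119, -0.0112]     # MPa
    alpha: [2.244, -1.081]
  cancer:
    model: ogden
    mu: [0.04238, -0.0224]     # MPa
    alpha: [2.244, -1.081]
protocol:
  n_positions: 5
  depths: [2.0, 4.0]           # mm
  increments: 4
nodule:
  shape: circle
  depth: 18                    # mm, centre depth
  x: 30                        # mm
  diameter: 10                 # mm
noise:
  sigma: 0.0                   # fraction of per-profile max force
  contact_offset: 0.0          # mm
  seed: 1
library:
  depths: [18]
  diameters: [8, 10, 14]
  smoothing: 0
solver:
  mode: displacement
  penalty_factor: 200
seed: 1
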