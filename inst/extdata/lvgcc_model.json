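{
  "schema": "phorescreen-model/1",
  "name": "L-VGCC-sixfeature",
  "require_all": true,
  "features": [
    {
      "label": "HBD1",
      "kind": "donor",
      "center": [1.58903398606481, -0.78137643386919, -1.27425867558705],
      "radius": 1.5,
      "direction": [0.0693637204779605, 0.153291358955717, -0.985743594222638],
      "source_atoms": 8
    },
    {
      "label": "HBD2",
      "kind": "donor",
      "center": [0.450458947022618, -1.09305570066961, -3.53899468363115],
      "radius": 1.5,
      "direction": [0.533260181396073, 0.413999748566525, -0.737724736689967],
      "source_atoms": 28
    },
    {
      "label": "Hydrophobic1",
      "kind": "hydrophobic",
      "center": [-2.44194168628332, -0.189964450139182, -0.446646599425345],
      "radius": 1.5,
      "direction": {},
      "source_atoms": [12, 13, 14, 15, 16, 17]
    },
    {
      "label": "Hydrophobic2",
      "kind": "hydrophobic",
      "center": [-1.54205066368857, -5.58123575370898, 1.38806867193881],
      "radius": 1.5,
      "direction": {},
      "source_atoms": 1
    },
    {
      "label": "Hydrophobic3",
      "kind": "hydrophobic",
      "center": [-0.105453116183605, 1.90837747741283, -0.570196980770249],
      "radius": 1.5,
      "direction": {},
      "source_atoms": 18
    },
    {
      "label": "Hydrophobic4",
      "kind": "hydrophobic",
      "center": [2.99048822917555, 1.19182384051496, -0.353165739034529],
      "radius": 1.5,
      "direction": {},
      "source_atoms": 23
    },
    {
      "label": "Exclusion1",
      "kind": "exclusion",
      "center": [1.79712514749869, -0.321502357002039, -4.23148945825496],
      "radius": 1.2,
      "direction": {},
      "source_atoms": []
    },
    {
      "label": "Exclusion2",
      "kind": "exclusion",
      "center": [2.05023949121084, 0.148943545029967, -5.75216889370105],
      "radius": 1.2,
      "direction": {},
      "source_atoms": []
    }
  ]
}
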