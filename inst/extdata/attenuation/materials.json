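{
  "water": {
    "kind": "linear",
    "density": 1,
    "k_edges": []
  },
  "soft_tissue": {
    "kind": "linear",
    "density": 1.06,
    "k_edges": []
  },
  "cortical_bone": {
    "kind": "linear",
    "density": 1.92,
    "k_edges": []
  },
  "adipose": {
    "kind": "linear",
    "density": 0.95,
    "k_edges": []
  },
  "pmma": {
    "kind": "linear",
    "density": 1.19,
    "k_edges": []
  },
  "teflon": {
    "kind": "linear",
    "density": 2.2,
    "k_edges": []
  },
  "aluminum": {
    "kind": "linear",
    "density": 2.699,
    "k_edges": []
  },
  "iodine": {
    "kind": "mass",
    "density": null,
    "k_edges": [
      33.2
    ]
  },
  "gadolinium": {
    "kind": "mass",
    "density": null,
    "k_edges": [
      50.2
    ]
  }
}
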