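{
  "name": "ca1_inputs_default",
  "description": "Parcellation of monosynaptically labeled input sources to dorsal CA1 pyramidal neurons. Local ipsilateral CA1 is excluded because primarily and secondarily rabies-infected cells cannot be distinguished at the injection site.",
  "regions": [
    {"label": "CA3a", "group": "CA3", "hemispheres": ["ipsilateral", "contralateral"], "layers": [], "include": true},
    {"label": "CA3b", "group": "CA3", "hemispheres": ["ipsilateral", "contralateral"], "layers": [], "include": true},
    {"label": "CA3c", "group": "CA3", "hemispheres": ["ipsilateral", "contralateral"], "layers": [], "include": true},
    {"label": "LEC", "group": "EC", "hemispheres": ["ipsilateral"], "layers": [], "include": true},
    {"label": "MEC", "group": "EC", "hemispheres": ["ipsilateral"], "layers": [], "include": true},
    {"label": "SUB", "group": "SUB_complex", "hemispheres": ["ipsilateral"], "layers": ["pyramidal cell layer", "polymorphic layer", "molecular layer"], "include": true},
    {"label": "PreParaSUB", "group": "SUB_complex", "hemispheres": ["ipsilateral"], "layers": [], "include": true},
    {"label": "pCA1", "group": "CA1", "hemispheres": ["contralateral"], "layers": [], "include": true},
    {"label": "mCA1", "group": "CA1", "hemispheres": ["contralateral"], "layers": [], "include": true},
    {"label": "dCA1", "group": "CA1", "hemispheres": ["contralateral"], "layers": [], "include": true},
    {"label": "CA1_local", "group": "CA1", "hemispheres": ["ipsilateral"], "layers": [], "include": false},
    {"label": "MedianRaphe", "group": "subcortical", "hemispheres": ["ipsilateral"], "layers": [], "include": true},
    {"label": "MS-DB", "group": "subcortical", "hemispheres": ["ipsilateral"], "layers": [], "include": true}
  ]
}
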