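{
  "system_label": "GATT GA-syn",
  "bright_state_energy_eV": 5.00,
  "states": [
    {"label": "S4", "character": "LE", "transition_note": "pipi* on G, bright", "energy_eV": 5.00, "oscillator_strength": 0.056, "wavelength_nm": 248.0},
    {"label": "S7", "character": "CT", "transition_note": "A to TT charge transfer (G+. ATT-.)", "energy_eV": 5.32, "oscillator_strength": 0.000425, "wavelength_nm": 233.1},
    {"label": "S10", "character": "CT", "transition_note": "G to A charge transfer (G+. A-.)", "energy_eV": 5.60, "oscillator_strength": 0.015, "wavelength_nm": 221.4}
  ],
  "points": [
    {"name": "FC", "kind": "minimum", "energy_eV": 5.00, "provenance": "printed (vertical bright excitation at the ground-state geometry)"},
    {"name": "G*", "kind": "minimum", "energy_eV": null, "provenance": "absolute energy not reported"},
    {"name": "G+A-", "kind": "minimum", "energy_eV": null, "provenance": "absolute energy not reported"},
    {"name": "MECP_G", "kind": "MECP", "energy_eV": null, "provenance": "absolute energy not reported"},
    {"name": "MECP_AG", "kind": "MECP", "energy_eV": null, "provenance": "absolute energy not reported"}
  ],
  "gaps": [
    {"from": "G*", "to": "MECP_G", "delta_eV": 0.15, "provenance": "printed"},
    {"from": "G+A-", "to": "MECP_AG", "delta_eV": 0.42, "provenance": "printed"}
  ]
}
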