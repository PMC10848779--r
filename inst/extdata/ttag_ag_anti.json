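{
  "system_label": "TTAG AG-anti",
  "bright_state_energy_eV": 4.95,
  "states": [
    {"label": "S1", "character": "LE", "transition_note": "pipi* on G, lowest bright state", "energy_eV": 4.95, "oscillator_strength": 0.097, "wavelength_nm": 250.7},
    {"label": "S2", "character": "LE", "transition_note": "locally excited", "energy_eV": 5.07, "oscillator_strength": 0.00104, "wavelength_nm": 244.5},
    {"label": "S3", "character": "LE", "transition_note": "locally excited", "energy_eV": 5.12, "oscillator_strength": 0.00165, "wavelength_nm": 242.0},
    {"label": "S4", "character": "LE", "transition_note": "locally excited", "energy_eV": 5.15, "oscillator_strength": 0.070, "wavelength_nm": 240.7},
    {"label": "S5", "character": "LE", "transition_note": "locally excited", "energy_eV": 5.28, "oscillator_strength": 0.00806, "wavelength_nm": 234.7},
    {"label": "S6", "character": "CT", "transition_note": "G to A charge transfer (A-. G+.)", "energy_eV": 5.40, "oscillator_strength": 0.388, "wavelength_nm": 229.4}
  ],
  "points": [
    {"name": "FC", "kind": "minimum", "energy_eV": 4.95, "provenance": "printed (vertical bright excitation at the ground-state geometry)"},
    {"name": "G*", "kind": "minimum", "energy_eV": 4.27, "provenance": "printed"},
    {"name": "A-G+", "kind": "minimum", "energy_eV": 4.15, "provenance": "derived-from-text (4.27 - 0.12)"},
    {"name": "TT-AG+", "kind": "minimum", "energy_eV": 2.93, "provenance": "derived-from-text (4.15 - 1.22)"},
    {"name": "MECP_G", "kind": "MECP", "energy_eV": 5.02, "provenance": "derived-from-text (4.27 + 0.75)"},
    {"name": "MECP_AG", "kind": "MECP", "energy_eV": 5.33, "provenance": "derived-from-text (4.27 - 0.12 + 1.18)"},
    {"name": "MECP_CPD", "kind": "MECP", "energy_eV": 2.98, "provenance": "derived-from-text (TT-AG+ plus a representative 0.05 eV barrier within the printed < 0.1 eV bound)", "geometry_notes": {"C5_C5_A": 2.55, "C6_C6_A": 1.56}}
  ],
  "gaps": [
    {"from": "G*", "to": "MECP_G", "delta_eV": 0.75, "provenance": "printed"},
    {"from": "G*", "to": "A-G+", "delta_eV": -0.12, "provenance": "printed"},
    {"from": "A-G+", "to": "MECP_AG", "delta_eV": 1.18, "provenance": "printed"},
    {"from": "A-G+", "to": "TT-AG+", "delta_eV": -1.22, "provenance": "printed"},
    {"from": "TT-AG+", "to": "MECP_CPD", "delta_eV": 0.05, "provenance": "derived (printed only as < 0.1 eV)"}
  ]
}
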