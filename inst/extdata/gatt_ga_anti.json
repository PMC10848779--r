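{
  "system_label": "GATT GA-anti",
  "bright_state_energy_eV": null,
  "states": [
    {"label": "S10", "character": "CT", "transition_note": "A to TT charge transfer (G+. ATT-.), lowest CT at this geometry", "energy_eV": 5.81, "oscillator_strength": null, "wavelength_nm": 213.4}
  ],
  "points": [
    {"name": "FC", "kind": "minimum", "energy_eV": 5.81, "provenance": "printed (vertical CT excitation at the ground-state geometry)"},
    {"name": "G*", "kind": "minimum", "energy_eV": null, "provenance": "absolute energy not reported"},
    {"name": "G+A-", "kind": "minimum", "energy_eV": null, "provenance": "absolute energy not reported"},
    {"name": "MECP_G", "kind": "MECP", "energy_eV": null, "provenance": "absolute energy not reported"},
    {"name": "MECP_AG", "kind": "MECP", "energy_eV": null, "provenance": "absolute energy not reported"}
  ],
  "gaps": [
    {"from": "G*", "to": "MECP_G", "delta_eV": 0.50, "provenance": "printed"},
    {"from": "G*", "to": "G+A-", "delta_eV": -0.9, "provenance": "printed (driving force for the first electron transfer)"},
    {"from": "G+A-", "to": "MECP_AG", "delta_eV": -0.25, "provenance": "printed (MECP below the CT minimum)"}
  ]
}
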