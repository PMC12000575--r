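{
  "type": "confined",
  "comment": "Structural water bilayer in gypsum: two O-H dipole species with calibrated local fields, angles to the confining b-axis from neutron diffraction, and the confinement-corrected water number density.",
  "dipoles": [
    {"label": "O-H_A", "theta_deg": 69.60, "E_HB_V_per_nm": 5.33, "N_m3": 4.06e28},
    {"label": "O-H_B", "theta_deg": 9.37, "E_HB_V_per_nm": 3.82, "N_m3": 4.06e28}
  ],
  "series": {
    "total_epsilon": 3.68,
    "fraction_water": 0.40
  }
}
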