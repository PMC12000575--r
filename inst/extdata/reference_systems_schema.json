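{
  "schema_version": 1,
  "columns": ["system", "temperature_K", "isotope", "bond_label", "wavenumber_cm1", "d_corrected_A", "sigma_d_A", "d_preconversion_A", "provenance"],
  "column_classes": {
    "system": "character",
    "temperature_K": "numeric",
    "isotope": "character",
    "bond_label": "character",
    "wavenumber_cm1": "numeric",
    "d_corrected_A": "numeric",
    "sigma_d_A": "numeric",
    "d_preconversion_A": "numeric",
    "provenance": "character"
  }
}
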