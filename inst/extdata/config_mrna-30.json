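{
  "vaccine": {
    "name": "mRNA-30",
    "rna_per_dose": 30,
    "doses_per_person": 2,
    "utp_type": "modified",
    "feasible_scale": 30
  },
  "process": {
    "volume": 30,
    "titre": 5,
    "nominal_recovery": 0.56,
    "failure_rate": 0.05,
    "residual_loss_factor": 0.9252068,
    "design_titre": 5,
    "capacity_anchors": [
      {
        "volume": 1,
        "batches_per_year": 471,
        "batch_duration_h": 41
      },
      {
        "volume": 30,
        "batches_per_year": 444,
        "batch_duration_h": 48.2
      }
    ]
  },
  "cost": {
    "cleancap_price": 3000,
    "mod_utp_price": 4700,
    "labour_rate": 20,
    "qc_fraction": 0.5,
    "materials_other_per_g": 2950,
    "cleancap_per_g_rna": 1,
    "modutp_per_g_rna": 0.45,
    "consumables_per_batch_ref": 340000,
    "consumables_scale_exponent": 0.45,
    "consumables_ref_volume": 30,
    "labour_hours_per_batch": 150,
    "capex_ref": 76100000,
    "capex_exponent": 0.5,
    "capex_ref_volume": 30,
    "depreciation_years": 10
  },
  "demand": {
    "annual_doses": 8000000000,
    "population": 7800000000,
    "doses_per_person": 2
  }
}
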