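{
  "refrigerated": {
    "truck": "refrigerated",
    "preset": "derived",
    "C0_material": 12333.58,
    "C0_labor": 836.57,
    "diesel_price": 0.72,
    "consumption": 3.6,
    "asset_cost": 14285.71,
    "depreciation_rate": 0.2,
    "annual_minutes": 158400,
    "wage_per_period": 14.29,
    "overtime_multiplier": 2,
    "speed": 1,
    "load_mass": 4.2,
    "C1": 0.2,
    "C2": 0.0180375126262626,
    "wage_rate": 0.026462962962963
  },
  "nonrefrigerated": {
    "truck": "nonrefrigerated",
    "preset": "derived",
    "C0_material": 12333.58,
    "C0_labor": 708.57,
    "diesel_price": 0.72,
    "consumption": 9,
    "asset_cost": 14285.71,
    "depreciation_rate": 0.2,
    "annual_minutes": 158400,
    "wage_per_period": 14.29,
    "overtime_multiplier": 2,
    "speed": 1,
    "load_mass": 4.2,
    "C1": 0.08,
    "C2": 0.0180375126262626,
    "wage_rate": 0.026462962962963
  }
}
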