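{
  "comment": "Published range-wide component areas (km^2) used as inputs to the habitat and gap bookkeeping functions.",
  "breeding_binary_km2": 2212,
  "breeding_refined_km2": 502,
  "terrestrial_km2": 2229,
  "protected_km2": 819,
  "projected_development_km2": 956,
  "projected_development_lt50_km2": 218,
  "projected_development_ge50_km2": 737
}
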