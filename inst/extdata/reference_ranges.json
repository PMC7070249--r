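{
  "_comment": "Normal ranges for healthy adult level walking (group mean +/- 2 s). Visual reference for reading reports, not medical criteria.",
  "ankle_rom_deg": {"min": 52, "max": 92, "unit": "deg"},
  "stride_length_m": {"min": 0.93, "max": 1.45, "unit": "m"},
  "cadence_spm": {"min": 90, "max": 134, "unit": "steps/min"},
  "walking_speed_mps": {"min": 0.99, "max": 1.69, "unit": "m/s"},
  "stance_ratio": {"min": 0.45, "max": 0.73, "unit": ""},
  "max_foot_elevation_m": {"min": 0.12, "max": 0.36, "unit": "m"},
  "gait_symmetry_stance": {"min": 0.81, "max": 1.0, "unit": ""}
}
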