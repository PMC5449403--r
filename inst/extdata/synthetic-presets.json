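{
  "s1_like": {
    "design": "S1",
    "effect_extent_m": 300,
    "dispersion": 0.25,
    "archetypes": [
      {"name": "pioneer grass A", "role": "pioneer", "baseline": 2.0, "multiplier": 10.0,
       "midpoint_m": 60, "steepness": 2.5, "cover_per_stalk": 0.6, "cover_shape": 4, "occupancy": 1.0},
      {"name": "pioneer grass B", "role": "pioneer", "baseline": 1.8, "multiplier": 9.0,
       "midpoint_m": 60, "steepness": 2.5, "cover_per_stalk": 0.5, "cover_shape": 4, "occupancy": 1.0},
      {"name": "pioneer forb C", "role": "pioneer", "baseline": 1.5, "multiplier": 8.0,
       "midpoint_m": 55, "steepness": 2.5, "cover_per_stalk": 0.4, "cover_shape": 4, "occupancy": 1.0},
      {"name": "dominant shrub D", "role": "original_dominant", "baseline": 12.0, "multiplier": 0.08,
       "midpoint_m": 80, "steepness": 3.0, "cover_per_stalk": 0.8, "cover_shape": 4, "occupancy": 1.0},
      {"name": "dominant forb E", "role": "original_dominant", "baseline": 10.0, "multiplier": 0.10,
       "midpoint_m": 80, "steepness": 3.0, "cover_per_stalk": 0.6, "cover_shape": 4, "occupancy": 1.0},
      {"name": "accompanying forb F", "role": "accompanying", "baseline": 1.0, "multiplier": 0.05,
       "midpoint_m": 40, "steepness": 2.5, "cover_per_stalk": 0.3, "cover_shape": 4, "occupancy": 0.6},
      {"name": "accompanying forb G", "role": "accompanying", "baseline": 0.8, "multiplier": 0.05,
       "midpoint_m": 40, "steepness": 2.5, "cover_per_stalk": 0.3, "cover_shape": 4, "occupancy": 0.6},
      {"name": "accompanying herb H", "role": "accompanying", "baseline": 0.6, "multiplier": 0.05,
       "midpoint_m": 40, "steepness": 2.5, "cover_per_stalk": 0.3, "cover_shape": 4, "occupancy": 0.6}
    ]
  },
  "s2_like": {
    "design": "S2",
    "effect_extent_m": 100,
    "dispersion": 0.25,
    "archetypes": [
      {"name": "pioneer grass A", "role": "pioneer", "baseline": 2.0, "multiplier": 8.0,
       "midpoint_m": 25, "steepness": 2.5, "cover_per_stalk": 0.5, "cover_shape": 4, "occupancy": 1.0},
      {"name": "pioneer forb B", "role": "pioneer", "baseline": 1.5, "multiplier": 7.0,
       "midpoint_m": 25, "steepness": 2.5, "cover_per_stalk": 0.4, "cover_shape": 4, "occupancy": 1.0},
      {"name": "dominant shrub C", "role": "original_dominant", "baseline": 12.0, "multiplier": 0.10,
       "midpoint_m": 30, "steepness": 3.0, "cover_per_stalk": 0.8, "cover_shape": 4, "occupancy": 1.0},
      {"name": "dominant forb D", "role": "original_dominant", "baseline": 9.0, "multiplier": 0.12,
       "midpoint_m": 30, "steepness": 3.0, "cover_per_stalk": 0.6, "cover_shape": 4, "occupancy": 1.0},
      {"name": "accompanying forb E", "role": "accompanying", "baseline": 0.9, "multiplier": 0.08,
       "midpoint_m": 15, "steepness": 2.5, "cover_per_stalk": 0.3, "cover_shape": 4, "occupancy": 0.6},
      {"name": "accompanying herb F", "role": "accompanying", "baseline": 0.7, "multiplier": 0.08,
       "midpoint_m": 15, "steepness": 2.5, "cover_per_stalk": 0.3, "cover_shape": 4, "occupancy": 0.6}
    ]
  },
  "null": {
    "design": "S1",
    "effect_extent_m": null,
    "dispersion": 0.25,
    "archetypes": [
      {"name": "grass A", "role": "accompanying", "baseline": 6.0, "multiplier": 1.0,
       "midpoint_m": 100, "steepness": 2.5, "cover_per_stalk": 0.5, "cover_shape": 4, "occupancy": 1.0},
      {"name": "shrub B", "role": "accompanying", "baseline": 10.0, "multiplier": 1.0,
       "midpoint_m": 100, "steepness": 2.5, "cover_per_stalk": 0.7, "cover_shape": 4, "occupancy": 1.0},
      {"name": "forb C", "role": "accompanying", "baseline": 3.0, "multiplier": 1.0,
       "midpoint_m": 100, "steepness": 2.5, "cover_per_stalk": 0.4, "cover_shape": 4, "occupancy": 0.8},
      {"name": "herb D", "role": "accompanying", "baseline": 1.5, "multiplier": 1.0,
       "midpoint_m": 100, "steepness": 2.5, "cover_per_stalk": 0.3, "cover_shape": 4, "occupancy": 0.8}
    ]
  }
}
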