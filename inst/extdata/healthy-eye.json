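{
  "media": [
    {"name": "cornea", "thickness_mm": 0.55544, "group_index": 1.387, "reflectivity": 0.8},
    {"name": "aqueous", "thickness_mm": 3.03456, "group_index": 1.342, "reflectivity": 0.3},
    {"name": "lens", "thickness_mm": 4.02, "group_index": 1.408, "reflectivity": 0.35},
    {"name": "vitreous", "thickness_mm": 16.32, "group_index": 1.341, "reflectivity": 0.35}
  ],
  "retina": {
    "bruch_offset_um": 0,
    "rpe_elevation_um": 0,
    "detachment_height_um": 0,
    "rpe_reflectivity": 0.55,
    "bruch_reflectivity": 0.12
  },
  "pathology": {
    "opacity_position_mm": null,
    "opacity_attenuation": 0,
    "opacity_lateral_extent_mm": null
  }
}
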