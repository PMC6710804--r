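{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Eye phantom specification",
  "description": "Layered ground-truth eye model for simulated OCT biometry. Depths are millimetres from the anterior corneal apex; the four media must appear in anatomical order.",
  "type": "object",
  "required": ["media"],
  "properties": {
    "media": {
      "type": "array",
      "minItems": 4,
      "maxItems": 4,
      "items": {
        "type": "object",
        "required": ["name", "thickness_mm", "group_index", "reflectivity"],
        "properties": {
          "name": {"enum": ["cornea", "aqueous", "lens", "vitreous"]},
          "thickness_mm": {"type": "number", "exclusiveMinimum": 0},
          "group_index": {"type": "number", "minimum": 1.0, "maximum": 2.0},
          "reflectivity": {
            "type": "number", "minimum": 0, "maximum": 1,
            "description": "Relative amplitude of the specular interface at the medium's anterior surface"
          }
        }
      }
    },
    "retina": {
      "type": "object",
      "properties": {
        "bruch_offset_um": {"type": "number", "minimum": 0},
        "rpe_elevation_um": {"type": "number", "minimum": 0},
        "detachment_height_um": {"type": "number", "minimum": 0},
        "rpe_reflectivity": {"type": "number", "minimum": 0, "maximum": 1},
        "bruch_reflectivity": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "pathology": {
      "type": "object",
      "properties": {
        "opacity_position_mm": {
          "type": ["number", "null"],
          "description": "Axial position of a lens opacity; must lie inside the lens segment"
        },
        "opacity_attenuation": {"type": "number", "minimum": 0, "maximum": 1},
        "opacity_lateral_extent_mm": {"type": "number", "minimum": 0}
      }
    }
  }
}
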