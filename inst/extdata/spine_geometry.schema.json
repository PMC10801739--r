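{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "spine_geometry",
  "description": "Landmark-based lumbar spine geometry (L1-sacrum): six bodies with 47 labelled landmarks per lumbar vertebra (positions in millimetres in the owning body frame), world poses, mid-disc frames and facet contact definitions. Version 1.",
  "type": "object",
  "required": ["schema", "schema_version", "subject_id", "seed",
               "lordosis_deg", "fixed_body", "vertebrae", "disc_frames",
               "facet_contacts"],
  "properties": {
    "schema": {"const": "spine_geometry"},
    "schema_version": {"const": 1},
    "subject_id": {"type": "string"},
    "seed": {"type": "integer"},
    "lordosis_deg": {"type": "number", "minimum": 0, "maximum": 90},
    "fixed_body": {"const": "SA"},
    "vertebrae": {
      "type": "object",
      "minProperties": 6,
      "additionalProperties": {
        "type": "object",
        "required": ["level", "mass", "inertia", "pose", "landmarks"],
        "properties": {
          "level": {"enum": ["L1", "L2", "L3", "L4", "L5", "SA"]},
          "mass": {"type": "number", "exclusiveMinimum": 0},
          "inertia": {"type": "array", "items": {"type": "number"},
                      "minItems": 9, "maxItems": 9},
          "pose": {
            "type": "object",
            "required": ["R", "p"],
            "properties": {
              "R": {"type": "array", "items": {"type": "number"},
                    "minItems": 9, "maxItems": 9},
              "p": {"type": "array", "items": {"type": "number"},
                    "minItems": 3, "maxItems": 3}
            }
          },
          "landmarks": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id", "role", "x", "y", "z"],
              "properties": {
                "id": {"type": "string"},
                "role": {"enum": ["ligament_insertion", "facet_point",
                                  "endplate_point", "spinous_tip",
                                  "body_center"]},
                "x": {"type": "number"},
                "y": {"type": "number"},
                "z": {"type": "number"}
              }
            }
          }
        }
      }
    },
    "disc_frames": {"type": "object", "minProperties": 5},
    "facet_contacts": {"type": "array", "minItems": 10}
  }
}
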