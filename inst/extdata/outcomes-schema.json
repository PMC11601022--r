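{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "sf6mbw-outcomes-1",
  "title": "SF6 multiple-breath washout outcomes report",
  "type": "object",
  "required": ["schema", "frc_ml", "cev_ml", "lci_to", "eot_breath",
               "et_initial", "et_final", "et_sf6", "dead_space_ml"],
  "properties": {
    "schema": {"type": "string"},
    "software_version": {"type": "string"},
    "frc_ml": {"type": "number", "exclusiveMinimum": 0},
    "cev_ml": {"type": "number", "exclusiveMinimum": 0},
    "lci_to": {"type": "number", "exclusiveMinimum": 0},
    "eot_breath": {"type": "integer", "minimum": 1},
    "breath_count": {"type": "integer", "minimum": 1},
    "et_initial": {"type": "number"},
    "et_final": {"type": "number"},
    "et_sf6": {"type": "array", "items": {"type": "number"}},
    "dead_space_ml": {"type": "number", "minimum": 0},
    "clamped_fraction": {"type": "number", "minimum": 0, "maximum": 1},
    "washin_complete": {"type": "boolean"},
    "flags": {"type": "array", "items": {"type": "string"}},
    "config": {"type": "object"}
  }
}
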