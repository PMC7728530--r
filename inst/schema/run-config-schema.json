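{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dwellsurv run configuration",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "seed": {"type": "integer", "description": "root RNG seed"},
    "n_users": {"type": "integer", "minimum": 1},
    "missing_demographics": {"type": "integer", "minimum": 0},
    "platform_mix": {
      "type": "object",
      "properties": {
        "android": {"type": "number", "minimum": 0, "maximum": 1},
        "ios": {"type": "number", "minimum": 0, "maximum": 1}
      },
      "description": "proportions; must sum to 1"
    },
    "occupation_mix": {
      "type": "object",
      "description": "proportions over resident_physician, visiting_staff, medical_student, nurse, other; must sum to 1"
    },
    "active_cadence": {"enum": ["daily", "monthly"]},
    "trace_days": {"type": "integer", "minimum": 0},
    "registration_window": {
      "type": "array",
      "items": {"type": "string", "format": "date"},
      "minItems": 2,
      "maxItems": 2
    },
    "study_cutoff": {"type": "string", "format": "date"},
    "churn_hazards": {
      "type": "object",
      "description": "per stream (passive, active) then platform (android, ios): three non-negative daily hazards on days [0,7), [7,28), [28,inf)"
    },
    "geofence": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "radius_km": {"type": "number", "exclusiveMinimum": 0},
        "sample_interval_min": {"type": "number", "exclusiveMinimum": 0},
        "confirm_min": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "retention": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "gap_days": {"type": "integer", "minimum": 1},
        "install_window_days": {"type": "integer", "minimum": 1},
        "churn_anchor": {"enum": ["gap_start", "last_upload"]}
      }
    }
  }
}
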