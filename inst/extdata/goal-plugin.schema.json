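{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/smartcoach/goal-plugin.schema.json",
  "title": "SMART goal plugin",
  "description": "Self-contained care plan: weekly intervention plans per difficulty level, trigger rules and configuration. Unknown extra properties are preserved but ignored (forward compatible).",
  "type": "object",
  "required": ["format_version", "plugin_id", "title", "dimension",
               "difficulty_levels", "fallback_messages"],
  "properties": {
    "format_version": {"const": "1"},
    "plugin_id": {"type": "string", "minLength": 1},
    "title": {"type": "string"},
    "dimension": {"enum": ["cognitive", "physical", "social", "nutritional"]},
    "description": {"type": "string"},
    "requirements": {
      "type": "array",
      "items": {"type": "string"},
      "description": "Display-only joining requirements; never evaluated by the engine."
    },
    "difficulty_levels": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["level_name", "duration_weeks", "weekly_plans"],
        "properties": {
          "level_name": {"type": "string"},
          "duration_weeks": {"type": "integer", "minimum": 4, "maximum": 8},
          "weekly_plans": {
            "type": "array",
            "description": "Exactly one entry per week 1..duration_weeks.",
            "items": {
              "type": "array",
              "items": {"$ref": "#/definitions/intervention_requirement"}
            }
          }
        }
      }
    },
    "awareness_tips": {"type": "array", "items": {"type": "string"}},
    "fallback_messages": {
      "type": "array",
      "minItems": 1,
      "items": {"type": "string"},
      "description": "Plain general messages that must always accompany every goal configuration."
    }
  },
  "definitions": {
    "intervention_requirement": {
      "type": "object",
      "required": ["tool_type", "min_count", "max_count"],
      "properties": {
        "tool_type": {"type": "string"},
        "min_count": {"type": "integer", "minimum": 0},
        "max_count": {"type": "integer", "minimum": 0},
        "time_window": {
          "type": "object",
          "required": ["start", "end"],
          "properties": {
            "start": {"type": "string", "pattern": "^[0-2][0-9]:[0-5][0-9]$"},
            "end": {"type": "string", "pattern": "^[0-2][0-9]:[0-5][0-9]$"}
          },
          "description": "Half-open local wall-clock interval [start, end), within one day."
        },
        "trigger_condition": {
          "type": "object",
          "required": ["all"],
          "properties": {
            "all": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["field", "value"],
                "properties": {
                  "field": {"enum": ["room", "posture", "interacting_object",
                                     "emotion", "last_speech_command",
                                     "weather"]},
                  "value": {"type": "string"},
                  "min_duration_min": {"type": "number", "minimum": 0}
                }
              }
            }
          }
        },
        "tool_payload": {
          "description": "Opaque configuration blob passed to the tool."
        }
      }
    }
  }
}
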