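{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "pathglyph-1/interchange.schema.json",
  "title": "pathglyph interchange format (version pathglyph-1)",
  "description": "Binds measurement values to metabolic-map identifiers, geoms, aesthetics, sides and conditions. Files use the suffix 'metabolism.json'.",
  "type": "object",
  "required": ["version", "conditions", "layers", "series"],
  "properties": {
    "version": { "const": "pathglyph-1" },
    "conditions": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Condition names in display order (top-to-bottom for box stacks)."
    },
    "layers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["geom", "aesthetic", "column"],
        "properties": {
          "geom": { "enum": ["arrow", "metabolite", "box", "hist", "kde"] },
          "aesthetic": { "enum": ["color", "size", "y"] },
          "side": { "enum": ["left", "right", "hover"] },
          "column": { "type": "string" }
        },
        "additionalProperties": false
      }
    },
    "series": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["layer", "identifier", "condition", "values"],
        "properties": {
          "layer": { "type": "integer", "minimum": 1, "description": "1-based index into layers" },
          "identifier": { "type": "string", "description": "reaction or metabolite BiGG id" },
          "condition": { "type": "string" },
          "values": {
            "type": "array",
            "items": { "type": "number" },
            "minItems": 1,
            "description": "exactly one value for point geoms (arrow/metabolite/box); two or more for hist/kde"
          }
        },
        "additionalProperties": false
      }
    }
  },
  "additionalProperties": false
}
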