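{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "synthzoo/registry.schema.json",
  "title": "synthzoo model-metadata registry",
  "description": "A single JSON object keyed by model id; each value carries the three metadata sections. Version 1.0.",
  "type": "object",
  "propertyNames": {
    "pattern": "^[0-9]{5}(_[A-Z0-9]+)+$"
  },
  "additionalProperties": {
    "type": "object",
    "required": ["execution", "selection", "description"],
    "properties": {
      "execution": {
        "type": "object",
        "required": ["package_location", "generate_method_name"],
        "properties": {
          "package_location": { "type": "string" },
          "package_name": { "type": "string" },
          "weights_name": { "type": "string" },
          "weights_extension": { "type": "string" },
          "dependencies": {
            "type": "array",
            "items": {
              "oneOf": [
                { "type": "string", "minLength": 1 },
                {
                  "type": "object",
                  "required": ["name"],
                  "properties": {
                    "name": { "type": "string", "minLength": 1 },
                    "version": { "type": "string" }
                  }
                }
              ]
            }
          },
          "generate_method_name": { "type": "string", "minLength": 1 },
          "generate_args": { "type": "object" },
          "image_size": {
            "type": "array",
            "items": { "type": "integer", "minimum": 1 },
            "minItems": 3,
            "maxItems": 3
          },
          "latent_dim": { "type": "integer", "minimum": 0 },
          "value_range": {
            "type": "array",
            "items": { "type": "number" },
            "minItems": 2,
            "maxItems": 2
          }
        }
      },
      "selection": {
        "type": "object",
        "properties": {
          "performance": { "type": "object" },
          "keywords": {
            "type": "array",
            "items": { "type": "string", "minLength": 1 }
          }
        }
      },
      "description": {
        "type": "object",
        "required": ["title"],
        "properties": {
          "title": { "type": "string", "minLength": 1 },
          "modality": { "type": "string" },
          "output_type": { "type": "string" },
          "training_dataset": { "type": "string" },
          "license": { "type": "string" },
          "date": { "type": "string", "format": "date" },
          "publication": { "type": "string" }
        }
      }
    }
  }
}
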