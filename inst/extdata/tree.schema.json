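{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/retree/tree.schema.json",
  "title": "retree classification-tree interchange format",
  "description": "Canonical JSON serialization of a mixed classification tree. Instances satisfying a node's test are always routed to 'left' (recorded in 'semantics'). Numbers are written in shortest round-trip decimal form; keys appear in the order given here.",
  "type": "object",
  "required": ["format_version", "semantics", "class_levels", "attributes", "config", "root"],
  "properties": {
    "format_version": { "const": "1.0" },
    "semantics": {
      "type": "object",
      "required": ["satisfying_instances"],
      "properties": { "satisfying_instances": { "const": "left" } }
    },
    "class_levels": {
      "type": "array", "items": { "type": "string" },
      "minItems": 1, "uniqueItems": true
    },
    "attributes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "kind", "ignored"],
        "properties": {
          "name": { "type": "string" },
          "kind": { "enum": ["continuous", "nominal"] },
          "ignored": { "type": "boolean" }
        }
      }
    },
    "config": {
      "type": "object",
      "required": ["families", "min_node_size", "max_depth", "max_nodes",
                   "entropy_threshold", "suggestion_k", "max_pairs"],
      "properties": {
        "families": {
          "type": "array",
          "items": { "enum": ["c45", "tsp", "wtsp"] },
          "minItems": 1
        },
        "min_node_size": { "type": "integer", "minimum": 1 },
        "max_depth": { "type": "integer", "minimum": 1 },
        "max_nodes": { "type": "integer", "minimum": 1 },
        "entropy_threshold": { "type": "number", "minimum": 0 },
        "suggestion_k": { "type": "integer", "minimum": 1 },
        "max_pairs": { "type": ["integer", "null"], "minimum": 2 }
      }
    },
    "root": { "$ref": "#/definitions/node" }
  },
  "definitions": {
    "node": {
      "oneOf": [
        {
          "type": "object",
          "required": ["kind", "predicted_class", "train_counts"],
          "properties": {
            "kind": { "const": "leaf" },
            "predicted_class": { "type": "string" },
            "train_counts": { "$ref": "#/definitions/counts" }
          }
        },
        {
          "type": "object",
          "required": ["kind", "test", "train_counts", "left", "right"],
          "properties": {
            "kind": { "const": "internal" },
            "test": { "$ref": "#/definitions/test" },
            "train_counts": { "$ref": "#/definitions/counts" },
            "left": { "$ref": "#/definitions/node" },
            "right": { "$ref": "#/definitions/node" }
          }
        }
      ]
    },
    "counts": {
      "type": "array",
      "items": { "type": "integer", "minimum": 0 },
      "description": "One entry per class level, in class_levels order; children must sum to their parent elementwise."
    },
    "test": {
      "oneOf": [
        {
          "type": "object",
          "required": ["family", "attribute", "threshold", "repr"],
          "properties": {
            "family": { "const": "c45" },
            "attribute": { "type": "string" },
            "threshold": { "type": "number" },
            "repr": { "type": "string" }
          },
          "description": "Left iff attribute >= threshold."
        },
        {
          "type": "object",
          "required": ["family", "attribute", "category", "repr"],
          "properties": {
            "family": { "const": "c45" },
            "attribute": { "type": "string" },
            "category": { "type": "string" },
            "repr": { "type": "string" }
          },
          "description": "Left iff attribute == category; out-of-vocabulary values go right."
        },
        {
          "type": "object",
          "required": ["family", "attribute1", "attribute2", "repr"],
          "properties": {
            "family": { "const": "tsp" },
            "attribute1": { "type": "string" },
            "attribute2": { "type": "string" },
            "repr": { "type": "string" }
          },
          "description": "Left iff attribute1 < attribute2 (strict; ties go right)."
        },
        {
          "type": "object",
          "required": ["family", "attribute1", "attribute2", "weight", "repr"],
          "properties": {
            "family": { "const": "wtsp" },
            "attribute1": { "type": "string" },
            "attribute2": { "type": "string" },
            "weight": { "type": "number", "exclusiveMinimum": 0 },
            "repr": { "type": "string" }
          },
          "description": "Left iff attribute1 < weight * attribute2 (strict; ties go right)."
        }
      ]
    }
  }
}
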