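{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/sbgndiff/diff-graph.schema.json",
  "title": "SBGN PD difference graph interchange format",
  "description": "Network-level difference between two SBML model versions: arrays of nodes and links. Nodes represent species, SBGN process nodes and compartments; links represent participation arcs. The bivesChange / bivesClass attributes carry the detected change class; absence means the element is unchanged.",
  "type": "object",
  "required": ["nodes", "links"],
  "properties": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "label": { "type": "string" },
          "compartment": {
            "type": "string",
            "description": "id of the compartment node containing this node"
          },
          "sboTerm": {
            "type": "string",
            "pattern": "^SBO:[0-9]{7}$",
            "description": "drives glyph selection; absent means the default glyph (unspecified entity)"
          },
          "bivesChange": {
            "enum": ["insert", "delete", "update", "move"]
          },
          "isCompartment": {
            "type": "boolean",
            "description": "extension attribute marking compartment nodes"
          }
        },
        "additionalProperties": true
      }
    },
    "links": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target"],
        "properties": {
          "source": { "type": "string", "minLength": 1 },
          "target": { "type": "string", "minLength": 1 },
          "class": {
            "enum": ["consumption", "production", "modulation", "stimulation",
                     "catalysis", "inhibition", "necessary-stimulation"],
            "description": "arc class; absent means the default arc (consumption)"
          },
          "bivesClass": {
            "enum": ["insert", "delete", "update", "move"]
          }
        },
        "additionalProperties": true
      }
    }
  },
  "additionalProperties": false
}
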