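{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "term index",
  "type": "object",
  "required": ["facets", "entries"],
  "properties": {
    "facets": { "type": "array", "items": { "type": "string" } },
    "entries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["ancestors", "id", "name", "obsolete", "slims", "synonyms"],
        "properties": {
          "ancestors": { "type": "array", "items": { "$ref": "#/definitions/curie" } },
          "id": { "$ref": "#/definitions/curie" },
          "name": { "type": "string" },
          "obsolete": { "type": "boolean" },
          "slims": {
            "type": "object",
            "additionalProperties": {
              "type": "array", "items": { "$ref": "#/definitions/curie" }
            }
          },
          "synonyms": { "type": "array", "items": { "type": "string" } }
        }
      }
    }
  },
  "definitions": {
    "curie": { "type": "string", "pattern": "^[A-Za-z]+:[A-Za-z0-9_]+$" }
  }
}
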