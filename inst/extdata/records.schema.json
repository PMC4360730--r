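{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "annotation records",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["record_id"],
    "properties": {
      "record_id": { "type": "string" },
      "assay_term": { "$ref": "#/definitions/curie" },
      "biosample_term": { "$ref": "#/definitions/curie" },
      "biosample_type": {
        "enum": ["tissue", "whole organism", "primary cell",
                 "immortalized cell line", "in vitro differentiated cell",
                 "induced pluripotent stem cell", "stem cell"]
      },
      "treatment_terms": {
        "type": "array", "items": { "$ref": "#/definitions/curie" }
      },
      "antibody": { "type": "string" },
      "status": { "type": "string" },
      "available_data": { "type": "array", "items": { "type": "string" } }
    }
  },
  "definitions": {
    "curie": { "type": "string", "pattern": "^[A-Za-z]+:[A-Za-z0-9_]+$" }
  }
}
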