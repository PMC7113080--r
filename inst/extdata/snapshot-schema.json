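{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "kbmatch knowledgebase snapshot",
  "description": "One JSON document per snapshot: one top-level array per entity type. Links between entities are by integer id. Coordinates are 1-based closed intervals on GRCh37.",
  "type": "object",
  "required": ["genes", "variants", "evidence"],
  "additionalProperties": false,
  "properties": {
    "format": {"const": "kb-snapshot"},
    "version": {"type": "integer", "minimum": 1},
    "reference_build": {"type": "string"},
    "genes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "name": {"type": "string"},
          "entrez_id": {"type": "integer"},
          "description": {"type": "string"},
          "variant_ids": {"type": "array", "items": {"type": "integer"}}
        }
      }
    },
    "variants": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "gene_id": {"type": "integer"},
          "name": {"type": "string"},
          "aliases": {"type": "array", "items": {"type": "string"}},
          "variant_types": {"type": "array", "items": {"type": "string"}},
          "coordinates": {
            "type": "object",
            "properties": {
              "reference_build": {"type": "string"},
              "chromosome": {"type": "string"},
              "start": {"type": "integer", "minimum": 1},
              "stop": {"type": "integer", "minimum": 1},
              "reference_bases": {"type": "string", "pattern": "^[ACGTN]*$"},
              "variant_bases": {"type": "string", "pattern": "^[ACGTN]*$"},
              "chromosome2": {"type": "string"},
              "start2": {"type": "integer", "minimum": 1},
              "stop2": {"type": "integer", "minimum": 1},
              "representative_transcript": {"type": "string"}
            }
          },
          "evidence_ids": {"type": "array", "items": {"type": "integer"}},
          "assertion_ids": {"type": "array", "items": {"type": "integer"}}
        }
      }
    },
    "variant_groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "name": {"type": "string"},
          "variant_ids": {"type": "array", "items": {"type": "integer"}}
        }
      }
    },
    "evidence": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "variant_id", "status"],
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "variant_id": {"type": "integer"},
          "status": {"enum": ["accepted", "submitted", "rejected"]},
          "evidence_level": {"enum": ["A", "B", "C", "D", "E"]},
          "evidence_direction": {"type": "string"},
          "clinical_significance": {"type": "string"},
          "disease": {"type": "object"},
          "drugs": {"type": "array", "items": {"type": "object"}},
          "source_id": {"type": "integer"},
          "rating": {"type": "integer", "minimum": 1, "maximum": 5}
        }
      }
    },
    "assertions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "variant_id", "status"],
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "status": {"enum": ["accepted", "submitted", "rejected"]},
          "amp_category": {"type": "string"},
          "variant_id": {"type": "integer"},
          "evidence_ids": {"type": "array", "items": {"type": "integer"}},
          "disease": {"type": "object"},
          "drugs": {"type": "array", "items": {"type": "object"}}
        }
      }
    },
    "sources": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "citation": {"type": "string"},
          "source_type": {"type": "string"},
          "citation_id": {"type": "string"}
        }
      }
    },
    "users": {"type": "array", "items": {"type": "object", "required": ["id"]}},
    "organizations": {"type": "array", "items": {"type": "object", "required": ["id"]}}
  }
}
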