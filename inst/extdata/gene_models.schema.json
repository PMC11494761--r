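{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Gene-model JSON dialect",
  "description": "Gene/transcript/exon/CDS models with 1-based inclusive genomic coordinates. Exons must be sorted ascending and non-overlapping; cds_start/cds_end must fall within the exon union; at most one transcript per gene may set canonical.",
  "type": "object",
  "required": ["genes"],
  "properties": {
    "genes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["symbol", "contig", "start", "end", "transcripts"],
        "properties": {
          "symbol": {"type": "string"},
          "contig": {"type": "string"},
          "start": {"type": "integer", "minimum": 1},
          "end": {"type": "integer", "minimum": 1},
          "description": {"type": "string"},
          "transcripts": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["id", "strand", "exons", "cds_start", "cds_end"],
              "properties": {
                "id": {"type": "string"},
                "strand": {"enum": ["+", "-"]},
                "canonical": {"type": "boolean"},
                "cds_start": {"type": "integer", "minimum": 1},
                "cds_end": {"type": "integer", "minimum": 1},
                "exons": {
                  "type": "array",
                  "minItems": 1,
                  "items": {
                    "type": "object",
                    "required": ["start", "end"],
                    "properties": {
                      "start": {"type": "integer", "minimum": 1},
                      "end": {"type": "integer", "minimum": 1}
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
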