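{
  "schema_version": "1.0",
  "disorder_group": "aortic",
  "nodes": [
    {
      "id": "cardiovascular_system",
      "dimension": "location",
      "kind": "System",
      "label": "Cardiovascular system",
      "attributes": []
    },
    {
      "id": "aorta",
      "dimension": "location",
      "kind": "Organ",
      "label": "Aorta",
      "attributes": []
    },
    {
      "id": "tunica_media",
      "dimension": "location",
      "kind": "Tissue",
      "label": "Tunica media",
      "attributes": []
    },
    {
      "id": "extracellular_matrix",
      "dimension": "location",
      "kind": "CellularComponent",
      "label": "Extracellular matrix",
      "attributes": []
    },
    {
      "id": "chr5",
      "dimension": "structural",
      "kind": "Chromosome",
      "label": "Chromosome 5",
      "attributes": []
    },
    {
      "id": "chr7",
      "dimension": "structural",
      "kind": "Chromosome",
      "label": "Chromosome 7",
      "attributes": []
    },
    {
      "id": "chr11",
      "dimension": "structural",
      "kind": "Chromosome",
      "label": "Chromosome 11",
      "attributes": []
    },
    {
      "id": "chr12",
      "dimension": "structural",
      "kind": "Chromosome",
      "label": "Chromosome 12",
      "attributes": []
    },
    {
      "id": "chr15",
      "dimension": "structural",
      "kind": "Chromosome",
      "label": "Chromosome 15",
      "attributes": []
    },
    {
      "id": "LOX",
      "dimension": "structural",
      "kind": "GeneElement",
      "label": "LOX",
      "attributes": {
        "symbol": "LOX"
      }
    },
    {
      "id": "ELN",
      "dimension": "structural",
      "kind": "GeneElement",
      "label": "ELN",
      "attributes": {
        "symbol": "ELN"
      }
    },
    {
      "id": "EFEMP2",
      "dimension": "structural",
      "kind": "GeneElement",
      "label": "EFEMP2",
      "attributes": {
        "symbol": "EFEMP2"
      }
    },
    {
      "id": "MFAP5",
      "dimension": "structural",
      "kind": "GeneElement",
      "label": "MFAP5",
      "attributes": {
        "symbol": "MFAP5"
      }
    },
    {
      "id": "FBN1",
      "dimension": "structural",
      "kind": "GeneElement",
      "label": "FBN1",
      "attributes": {
        "symbol": "FBN1"
      }
    },
    {
      "id": "elastic_lamella",
      "dimension": "entity",
      "kind": "ComplexEntity",
      "label": "Elastic lamella",
      "attributes": []
    },
    {
      "id": "elastic_fibers",
      "dimension": "entity",
      "kind": "ComplexEntity",
      "label": "Elastic fibers",
      "attributes": []
    },
    {
      "id": "microfibrils_complex",
      "dimension": "entity",
      "kind": "ComplexEntity",
      "label": "Microfibrils",
      "attributes": []
    },
    {
      "id": "elastin",
      "dimension": "entity",
      "kind": "Protein",
      "label": "Elastin",
      "attributes": []
    },
    {
      "id": "fibrillin_1",
      "dimension": "entity",
      "kind": "Protein",
      "label": "Fibrillin-1",
      "attributes": []
    },
    {
      "id": "efemp2_protein",
      "dimension": "entity",
      "kind": "Protein",
      "label": "EGF-containing fibulin-like extracellular matrix protein 2",
      "attributes": []
    },
    {
      "id": "lox_protein",
      "dimension": "entity",
      "kind": "Protein",
      "label": "Protein-lysine 6-oxidase",
      "attributes": []
    },
    {
      "id": "mfap5_protein",
      "dimension": "entity",
      "kind": "Protein",
      "label": "Microfibrillar-associated protein 5",
      "attributes": []
    },
    {
      "id": "elastic_fiber_assembly",
      "dimension": "pathway",
      "kind": "Pathway",
      "label": "Elastic fiber assembly",
      "attributes": []
    },
    {
      "id": "elastin_crosslinking",
      "dimension": "pathway",
      "kind": "Process",
      "label": "Elastin cross-linking",
      "attributes": []
    },
    {
      "id": "microfibril_assembly",
      "dimension": "pathway",
      "kind": "Process",
      "label": "Microfibril assembly",
      "attributes": []
    }
  ],
  "edges": [
    {
      "source": "aorta",
      "target": "cardiovascular_system",
      "kind": "part_of"
    },
    {
      "source": "tunica_media",
      "target": "aorta",
      "kind": "part_of"
    },
    {
      "source": "extracellular_matrix",
      "target": "tunica_media",
      "kind": "part_of"
    },
    {
      "source": "chr5",
      "target": "LOX",
      "kind": "contains"
    },
    {
      "source": "chr7",
      "target": "ELN",
      "kind": "contains"
    },
    {
      "source": "chr11",
      "target": "EFEMP2",
      "kind": "contains"
    },
    {
      "source": "chr12",
      "target": "MFAP5",
      "kind": "contains"
    },
    {
      "source": "chr15",
      "target": "FBN1",
      "kind": "contains"
    },
    {
      "source": "ELN",
      "target": "elastin",
      "kind": "codes_for"
    },
    {
      "source": "FBN1",
      "target": "fibrillin_1",
      "kind": "codes_for"
    },
    {
      "source": "LOX",
      "target": "lox_protein",
      "kind": "codes_for"
    },
    {
      "source": "EFEMP2",
      "target": "efemp2_protein",
      "kind": "codes_for"
    },
    {
      "source": "MFAP5",
      "target": "mfap5_protein",
      "kind": "codes_for"
    },
    {
      "source": "elastic_fibers",
      "target": "elastic_lamella",
      "kind": "component_of"
    },
    {
      "source": "elastin",
      "target": "elastic_fibers",
      "kind": "component_of"
    },
    {
      "source": "microfibrils_complex",
      "target": "elastic_fibers",
      "kind": "component_of"
    },
    {
      "source": "fibrillin_1",
      "target": "microfibrils_complex",
      "kind": "component_of"
    },
    {
      "source": "efemp2_protein",
      "target": "microfibrils_complex",
      "kind": "component_of"
    },
    {
      "source": "mfap5_protein",
      "target": "microfibrils_complex",
      "kind": "component_of"
    },
    {
      "source": "elastic_lamella",
      "target": "tunica_media",
      "kind": "located_in"
    },
    {
      "source": "lox_protein",
      "target": "extracellular_matrix",
      "kind": "located_in"
    },
    {
      "source": "elastic_fiber_assembly",
      "target": "elastin_crosslinking",
      "kind": "decomposes_into"
    },
    {
      "source": "elastic_fiber_assembly",
      "target": "microfibril_assembly",
      "kind": "decomposes_into"
    },
    {
      "source": "elastin",
      "target": "elastin_crosslinking",
      "kind": "takes_part_in",
      "role": "input"
    },
    {
      "source": "lox_protein",
      "target": "elastin_crosslinking",
      "kind": "takes_part_in",
      "role": "regulator"
    },
    {
      "source": "fibrillin_1",
      "target": "microfibril_assembly",
      "kind": "takes_part_in",
      "role": "input"
    },
    {
      "source": "mfap5_protein",
      "target": "microfibril_assembly",
      "kind": "takes_part_in",
      "role": "regulator"
    },
    {
      "source": "efemp2_protein",
      "target": "microfibril_assembly",
      "kind": "takes_part_in",
      "role": "regulator"
    }
  ]
}
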