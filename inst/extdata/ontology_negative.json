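{
  "name": "negative_regulation_context",
  "polarity": "negative",
  "nodes": [
    {"id": "negative_event", "label": "non-transcriptional regulation context", "count": null},
    {"id": "cell_cycle", "label": "cell cycle regulation", "count": 71},
    {"id": "dna_replication", "label": "DNA replication and repair", "count": 49},
    {"id": "translation", "label": "translation", "count": 35},
    {"id": "other_process", "label": "regulation of other biological processes", "count": null}
  ],
  "relations": [
    {"subject": "cell_cycle", "relation": "is_a", "object": "negative_event"},
    {"subject": "dna_replication", "relation": "is_a", "object": "negative_event"},
    {"subject": "translation", "relation": "is_a", "object": "negative_event"},
    {"subject": "other_process", "relation": "is_a", "object": "negative_event"}
  ],
  "patterns": [
    {"node_id": "cell_cycle", "keywords": ["spindle"]},
    {"node_id": "cell_cycle", "keywords": ["anaphase"]},
    {"node_id": "cell_cycle", "keywords": ["segregation"]},
    {"node_id": "cell_cycle", "keywords": ["mitosis"]},
    {"node_id": "cell_cycle", "keywords": ["cycle"]},
    {"node_id": "dna_replication", "keywords": ["replication"]},
    {"node_id": "dna_replication", "keywords": ["replication", "fork"]},
    {"node_id": "dna_replication", "keywords": ["dna", "repair"]},
    {"node_id": "translation", "keywords": ["translation"]},
    {"node_id": "translation", "keywords": ["codon"]},
    {"node_id": "translation", "keywords": ["ribosome"]},
    {"node_id": "other_process", "keywords": ["metabolism"]},
    {"node_id": "other_process", "keywords": ["mitochondrial"]},
    {"node_id": "other_process", "keywords": ["secretion"]}
  ]
}
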