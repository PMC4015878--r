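{
  "name": "transcription_rate_change",
  "polarity": "rate_change",
  "nodes": [
    {"id": "rate_change_event", "label": "transcriptional regulation rate change", "count": null},
    {"id": "chromatin_domains", "label": "chromatin domain events", "count": null},
    {"id": "nucleosome_dynamics", "label": "nucleosome composition and decomposition", "count": null},
    {"id": "chromosome_modification", "label": "chromosome structure modification", "count": null},
    {"id": "histone_modification", "label": "histone chemical modification", "count": null},
    {"id": "chromatin_remodeling", "label": "chromatin remodeling", "count": 12},
    {"id": "nuclear_change", "label": "nuclear change", "count": 13},
    {"id": "dna_structure", "label": "DNA structure changes", "count": 1},
    {"id": "chemical_reaction", "label": "chemical reaction", "count": 11},
    {"id": "transcription_process", "label": "transcription events", "count": null},
    {"id": "promoter_activity", "label": "promoter activity", "count": 101},
    {"id": "polymerase_activity", "label": "RNA polymerase activity", "count": null},
    {"id": "polymerase_binding", "label": "RNA polymerase binding", "count": null},
    {"id": "transcription_behavior", "label": "transcription behavior", "count": 343}
  ],
  "relations": [
    {"subject": "nucleosome_dynamics", "relation": "part_of", "object": "chromatin_domains"},
    {"subject": "chromosome_modification", "relation": "part_of", "object": "chromatin_domains"},
    {"subject": "histone_modification", "relation": "is_a", "object": "chromosome_modification"},
    {"subject": "chromatin_remodeling", "relation": "is_a", "object": "chromosome_modification"},
    {"subject": "nuclear_change", "relation": "part_of", "object": "chromatin_domains"},
    {"subject": "dna_structure", "relation": "part_of", "object": "chromatin_domains"},
    {"subject": "chemical_reaction", "relation": "part_of", "object": "histone_modification"},
    {"subject": "promoter_activity", "relation": "part_of", "object": "transcription_process"},
    {"subject": "polymerase_activity", "relation": "part_of", "object": "transcription_process"},
    {"subject": "polymerase_binding", "relation": "is_a", "object": "polymerase_activity"},
    {"subject": "transcription_behavior", "relation": "part_of", "object": "transcription_process"},
    {"subject": "rate_change_event", "relation": "result_from", "object": "chromatin_domains"},
    {"subject": "rate_change_event", "relation": "result_from", "object": "transcription_process"}
  ],
  "patterns": [
    {"node_id": "chromatin_domains", "keywords": ["chromatin"]},
    {"node_id": "nucleosome_dynamics", "keywords": ["nucleosome"]},
    {"node_id": "chromosome_modification", "keywords": ["chromosome", "structure"]},
    {"node_id": "histone_modification", "keywords": ["histone"]},
    {"node_id": "histone_modification", "keywords": ["ubiquitinate"]},
    {"node_id": "histone_modification", "keywords": ["methylation"]},
    {"node_id": "chemical_reaction", "keywords": ["acetylate"]},
    {"node_id": "chromatin_remodeling", "keywords": ["chromatin", "remodel"]},
    {"node_id": "nuclear_change", "keywords": ["nuclear"]},
    {"node_id": "dna_structure", "keywords": ["dna", "structure"]},
    {"node_id": "promoter_activity", "keywords": ["promoter", "activity"]},
    {"node_id": "promoter_activity", "keywords": ["promoter", "bind"]},
    {"node_id": "polymerase_activity", "keywords": ["polymerase"]},
    {"node_id": "transcription_behavior", "keywords": ["transcription"]},
    {"node_id": "transcription_behavior", "keywords": ["express"]},
    {"node_id": "transcription_behavior", "keywords": ["mrna"]}
  ]
}
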