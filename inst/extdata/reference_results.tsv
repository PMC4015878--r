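task	method	tp	fp	fn	tn	precision	recall	f1	accuracy
event_detection	tree_bioinfer_ontology	223	121	134	831	64.83	62.46	63.62	80.52
event_detection	tree_genereg_ontology	235	109	122	843	68.31	65.83	67.05	82.35
event_detection	tree_ratechange_ontology	276	107	81	845	72.06	77.31	74.59	85.64
event_detection	tree_combined_ontologies	277	99	80	853	73.67	77.59	75.58	86.33
event_detection	regulation_rule	335	223	22	729	60.04	93.84	73.22	81.28
event_detection	combined_rule	322	158	35	794	67.08	90.20	76.94	85.26
direct_evidence	baseline_features	131	88	80	58	59.82	62.09	60.93	52.94
direct_evidence	all_rules_features	149	102	62	44	59.36	70.62	64.50	54.06
direct_evidence	original_combined_features	175	121	36	25	59.12	82.94	69.03	56.02
direct_evidence	combined_features	185	122	26	24	60.26	87.68	71.43	58.54
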