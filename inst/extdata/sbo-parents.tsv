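# Snapshot subset of the Systems Biology Ontology is-a hierarchy
# (https://www.ebi.ac.uk/sbo/), restricted to the branches that drive
# glyph and arc selection: material entity, participant role, process.
# Format: child <TAB> parent, one is-a edge per line. Roots are absent
# from the child column's parents. Packaged so that term resolution
# needs no network access.
SBO:0000240	SBO:0000000
SBO:0000245	SBO:0000240
SBO:0000246	SBO:0000245
SBO:0000247	SBO:0000240
SBO:0000327	SBO:0000247
SBO:0000328	SBO:0000247
SBO:0000250	SBO:0000246
SBO:0000251	SBO:0000246
SBO:0000252	SBO:0000246
SBO:0000278	SBO:0000250
SBO:0000253	SBO:0000240
SBO:0000296	SBO:0000253
SBO:0000297	SBO:0000253
SBO:0000285	SBO:0000240
SBO:0000291	SBO:0000240
SBO:0000003	SBO:0000000
SBO:0000019	SBO:0000003
SBO:0000020	SBO:0000019
SBO:0000206	SBO:0000020
SBO:0000207	SBO:0000020
SBO:0000459	SBO:0000019
SBO:0000013	SBO:0000459
SBO:0000460	SBO:0000013
SBO:0000461	SBO:0000459
SBO:0000462	SBO:0000459
SBO:0000021	SBO:0000459
SBO:0000375	SBO:0000000
SBO:0000176	SBO:0000375
SBO:0000177	SBO:0000176
SBO:0000182	SBO:0000375
SBO:0000183	SBO:0000205
SBO:0000205	SBO:0000375
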