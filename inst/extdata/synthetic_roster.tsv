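taxon	group	deep
Homo	Metazoa	FALSE
Pan	Metazoa	FALSE
Mus	Metazoa	FALSE
Rattus	Metazoa	FALSE
Canis	Metazoa	FALSE
Bos	Metazoa	FALSE
Monodelphis	Metazoa	FALSE
Gallus	Metazoa	FALSE
Xenopus	Metazoa	FALSE
Danio	Metazoa	FALSE
Takifugu	Metazoa	FALSE
Ciona	Metazoa	FALSE
Drosophila	Metazoa	FALSE
Apis	Metazoa	FALSE
Daphnia	Metazoa	FALSE
Monosiga	Choanoflagellata	TRUE
Batrachochytrium	Fungi	TRUE
Cryptococcus	Fungi	FALSE
Ustilago	Fungi	FALSE
Aspergillus	Fungi	FALSE
Neurospora	Fungi	FALSE
Saccharomyces	Fungi	FALSE
Candida	Fungi	FALSE
Schizosaccharomyces	Fungi	FALSE
Entamoeba	Amoebozoa	FALSE
Dictyostelium	Amoebozoa	FALSE
Chlamydomonas	Viridiplantae	FALSE
Ostreococcus	Viridiplantae	FALSE
Physcomitrella	Viridiplantae	FALSE
Oryza	Viridiplantae	FALSE
Sorghum	Viridiplantae	FALSE
Populus	Viridiplantae	FALSE
Vitis	Viridiplantae	FALSE
Arabidopsis	Viridiplantae	FALSE
Cyanidioschyzon	Rhodophyta	TRUE
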