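(((((((((((Homo:0.1,Pan:0.1):0.1,(Mus:0.1,Rattus:0.1):0.1):0.1,(Canis:0.1,Bos:0.1):0.1):0.1,Monodelphis:0.1):0.1,(Gallus:0.1,(Xenopus:0.1,(Danio:0.1,Takifugu:0.1):0.1):0.1):0.1):0.1,Ciona:0.1):0.1,(Drosophila:0.1,(Apis:0.1,Daphnia:0.1):0.1):0.1):0.1,Monosiga:0.1):0.1,(Batrachochytrium:0.1,((Cryptococcus:0.1,Ustilago:0.1):0.1,((Aspergillus:0.1,Neurospora:0.1):0.1,((Saccharomyces:0.1,Candida:0.1):0.1,Schizosaccharomyces:0.1):0.1):0.1):0.1):0.1):0.1,(Entamoeba:0.1,Dictyostelium:0.1):0.1):0.1,(((Chlamydomonas:0.1,Ostreococcus:0.1):0.1,(Physcomitrella:0.1,((Oryza:0.1,Sorghum:0.1):0.1,((Populus:0.1,Vitis:0.1):0.1,Arabidopsis:0.1):0.1):0.1):0.1):0.1,Cyanidioschyzon:0.1):0.1);
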