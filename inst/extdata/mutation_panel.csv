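acaricide_group,gene,accession,codon_position,wild_aa,mutant_aa,wild_codon,mutant_codon,substituted_positions,wild_nt,mutant_nt,substitution_class,abbreviation
Organophosphate,Tuace,tetur19g00850,228,G,S,GGC,AGC,1,G,A,transition,G228S
Organophosphate,Tuace,tetur19g00850,228,G,A,GGC,TGC,1,G,T,transversion,G228A
Organophosphate,Tuace,tetur19g00850,309,A,S,GCT,TCT,1,G,T,transversion,A309S
Organophosphate,Tuace,tetur19g00850,391,A,T,GCA,ACA,1,G,A,transition,A391T
Organophosphate,Tuace,tetur19g00850,436,G,A,GGA,GCA,2,G,C,transversion,G436A
Organophosphate,Tuace,tetur19g00850,439,F,W,TTT,TGG,2;3,T,G,transversion,F439W
Organophosphate,Tuace,tetur19g00850,439,F,Y,TTT,TAT,2,T,A,transversion,F439Y
Pyrethroid,Tuvssc,Tetur34g00970,1022,L,V,CTC,GTC,1,C,G,transversion,L1022V
Pyrethroid,Tuvssc,Tetur34g00970,1376,A,D,GCT,GAT,2,C,A,transversion,A1376D
Pyrethroid,Tuvssc,Tetur34g00970,1704,F,I,TTC,ATC,1,T,A,transversion,F1704I
Abamectin,TuGluCl1,tetur02g04080,323,G,D,GGT,GAT,2,G,A,transition,G323D
Abamectin,TuGluCl3,tetur10g03090,326,G,E,GGA,GAA,2,G,A,transition,G326E
Etoxazole,TuCHS1,tetur03g08510,1017,I,F,ATT,TTT,1,A,T,transversion,I1017F
Bifenazate,TuCytB,YP_001795379.1,126,G,S,GGA,AGA,1,G,A,transition,G126S
Bifenazate,TuCytB,YP_001795379.1,136,I,T,ATT,ACT,2,T,C,transition,I136T
Bifenazate,TuCytB,YP_001795379.1,141,S,F,TCT,TTT,2,C,T,transition,S141F
Bifenazate,TuCytB,YP_001795379.1,161,D,G,GAT,GGT,2,A,G,transition,D161G
Bifenazate,TuCytB,YP_001795379.1,262,P,T,CCT,ACT,1,C,A,transversion,P262T
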