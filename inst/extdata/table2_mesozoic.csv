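genus,clade,age,institutional_id,no
Archaeopteryx,Basal Aves,Late Jurassic,BMNH 37001,88
Cathayornis,Enantiornithes,Early Cretaceous,IVPP V9769,89
Concornis,Enantiornithes,Early Cretaceous,LH 2814,91
Confuciusornis,Basal Aves,Early Cretaceous,GMV 2133,92
Eoalulavis,Enantiornithes,Early Cretaceous,LH 13500a,93
Eoconfuciusornis,Basal Aves,Early Cretaceous,IVPP V11977,94
Hongshanornis,Ornithuromorpha,Early Cretaceous,IVPP V14533,95
Iberomesornis,Enantiornithes,Early Cretaceous,LH 22,96
Longicrusavis,Ornithuromorpha,Early Cretaceous,PKUP V1069,97
Longipteryx,Enantiornithes,Early Cretaceous,IVPP V12325,98
Noguerornis,Enantiornithes,Early Cretaceous,LP 715 IEI,99
Ornithuromorpha indet,Ornithuromorpha,Early Cretaceous,FRDC-05-CM-021,100
Pengornis,Enantiornithes,Early Cretaceous,IVPP V15336,101
Protopteryx,Enantiornithes,Early Cretaceous,IVPP V11665,102
Rapaxavis,Enantiornithes,Early Cretaceous,DNHM D2522,103
Sapeornis,Basal Aves,Early Cretaceous,IVPP V13276,104
Vescornis,Enantiornithes,Early Cretaceous,NIGP 130722,105
Zhongjianornis,Basal Aves,Early Cretaceous,IVPP V15900,106
Gansus,Ornithuromorpha,Early Cretaceous,CAGM CM003,108
Anchiornis,Paraves,Early Cretaceous,LPM B00169,109
Bambiraptor,Dromaeosauridae,Late Cretaceous,AMNH FR30554,110
Falcarius,Therizinosauria,Early Cretaceous,UMNH-VP 14671,111
Neimongosaurus,Therizonosauria,Late Cretaceous,LH V0001,112
Oviraptor,Oviraptoridae,Late Cretaceous,AMNH FR 6517,113
Tyrannosaurus,Tyrannosauridae,Late Cretaceous,MOR 1125,114
Velociraptor,Dromaeosauridae,Late Cretaceous,IGM 100/976,115
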