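class	strain	genome_size_mbp
Alphaproteobacteria	Acidiphilium multivorum AIU301	3.58
Alphaproteobacteria	Ketogulonigenium vulgarum WSH 001	2.64
Alphaproteobacteria	Mesorhizobium australicum WSM2073	3.74
Alphaproteobacteria	Methylocapsa acidiphila B2	5.91
Alphaproteobacteria	Methyloferula stellata AR4	4.04
Alphaproteobacteria	Rhodovibrio salinarum DSM 9154	4.30
Alphaproteobacteria	Roseobacter litoralis Och 149	3.98
Alphaproteobacteria	Sphingobium japonicum UT26S 1	3.35
Alphaproteobacteria	Starkeya novella DSM 506	4.54
Alphaproteobacteria	Tistrella mobilis KA081020 065	3.74
Betaproteobacteria	Alicycliphilus denitrificans K601	4.76
Betaproteobacteria	Dechlorosoma suillum PS	3.63
Betaproteobacteria	Gallionella capsiferriformans ES 2	3.02
Betaproteobacteria	Herbaspirillum seropedicae SmR1	5.26
Betaproteobacteria	Nitrosospira multiformis ATCC 25196	3.04
Betaproteobacteria	Ramlibacter tataouinensis TTB310	3.88
Betaproteobacteria	Sideroxydans lithotrophicus ES 1	2.41
Betaproteobacteria	Snodgrassella alvi wkB2	2.99
Betaproteobacteria	Sulfuricella denitrificans skB26	2.86
Betaproteobacteria	Tetrathiobacter kashmirensis WT001	4.16
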