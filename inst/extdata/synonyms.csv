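alias,canonical
Sophoretin,Quercetin
Meletin,Quercetin
Robigenin,Kaempferol
Digitoflavone,Luteolin
Naringetol,Naringenin
β-sitosterol,Beta-sitosterol
4-hydroxy-3-methoxycinnamic acid,Ferulic acid
PKB,AKT1
RAC-alpha serine/threonine-protein kinase,AKT1
TNF-α,TNF
tumor necrosis factor alpha,TNF
interleukin-6,IL6
ERBB1,EGFR
HER1,EGFR
estrogen receptor alpha,ESR1
p53,TP53
COX-2,PTGS2
COX2,PTGS2
c-Jun,JUN
VEGF-A,VEGFA
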