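abbreviation,full_name,n_rings,tef,carcinogenic,enabled
Naph,naphthalene,2,0.001,FALSE,TRUE
Acy,acenaphthylene,3,0.001,FALSE,TRUE
Acen,acenaphthene,3,0.001,FALSE,TRUE
Fln,fluorene,3,0.001,FALSE,TRUE
Phe,phenanthrene,3,0.001,FALSE,TRUE
Ant,anthracene,3,0.01,FALSE,TRUE
Flt,fluoranthene,4,0.001,FALSE,TRUE
Pyr,pyrene,4,0.001,FALSE,TRUE
BaA,benzo[a]anthracene,4,0.1,TRUE,TRUE
CHR,chrysene,4,0.01,TRUE,TRUE
BbF,benzo[b]fluoranthene,5,0.1,TRUE,TRUE
BkF,benzo[k]fluoranthene,5,0.1,TRUE,TRUE
BaP,benzo[a]pyrene,5,1,TRUE,TRUE
IcP,indeno[1;2;3-cd]pyrene,6,0.1,TRUE,TRUE
DhA,dibenzo[a;h]anthracene,5,1,TRUE,TRUE
BgP,benzo[g;h;i]perylene,6,0.01,FALSE,TRUE
BeP,benzo[e]pyrene,5,0,FALSE,FALSE
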