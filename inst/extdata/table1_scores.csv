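sample_id,msi_status,mutation,cms_class,score_18gene,score_13gene,score_src
LIM2099,MSS,KRAS,CMS4,0.26,7.36,6.78
LS123,MSS,KRAS,CMS4,1.05,3.22,1.77
SW480,MSS,KRAS,CMS4,1.40,3.01,1.08
SW1417,MSS,BRAF,CMS4,0.89,0.13,1.22
SNU2CA,MSI,KRAS,CMS4,0.15,1.70,0.51
HCT116,MSI,KRAS,CMS4,0.14,0.77,-0.17
WiDr,MSS,BRAF,CMS3,0.06,0.78,1.10
HCA7,MSI,WT,CMS4,0.38,0.42,0.20
SW620,MSS,KRAS,CMS4,0.38,-0.36,-0.18
SNU2CB,MSI,KRAS,CMS3,-0.45,0.30,-0.42
SNU1411,MSS,KRAS,CMS3,0.32,-0.21,1.45
DIFI,MSS,WT,CMS2,-0.35,1.69,1.14
LoVo,MSI,KRAS,CMS1,-0.01,0.01,0.07
SW48,MSI,WT,CMS1,0.00,-0.17,-0.45
SW837,MSS,KRAS,CMS4,-0.59,0.32,-0.17
RW7213,MSS,KRAS,CMS2,1.00,-0.47,-0.41
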