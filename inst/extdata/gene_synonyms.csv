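canonical,synonym
cox1,cox1
cox1,COI
cox1,COX1
cox1,co1
cox2,cox2
cox2,COII
cox2,COX2
cox2,co2
cox3,cox3
cox3,COIII
cox3,COX3
cox3,co3
cob,cob
cob,cytb
cob,CYTB
cob,COB
nad1,nad1
nad1,ND1
nad2,nad2
nad2,ND2
nad3,nad3
nad3,ND3
nad4,nad4
nad4,ND4
nad4L,nad4L
nad4L,ND4L
nad4L,nad4l
nad5,nad5
nad5,ND5
nad6,nad6
nad6,ND6
atp6,atp6
atp6,ATP6
atp8,atp8
atp8,ATP8
rrnL,rrnL
rrnL,lrRNA
rrnL,16S
rrnL,l-rRNA
rrnL,rrn16
rrnS,rrnS
rrnS,srRNA
rrnS,12S
rrnS,s-rRNA
rrnS,rrn12
control_region,control_region
control_region,Control region
control_region,D-loop
control_region,d-loop
control_region,AT-rich region
control_region,A+T-rich region
trnA,trnA
trnR,trnR
trnN,trnN
trnD,trnD
trnC,trnC
trnQ,trnQ
trnE,trnE
trnG,trnG
trnH,trnH
trnI,trnI
trnL1,trnL1
trnL1,trnL1(CUN)
trnL1,trnL(CUN)
trnL2,trnL2
trnL2,trnL2(UUR)
trnL2,trnL(UUR)
trnK,trnK
trnM,trnM
trnF,trnF
trnP,trnP
trnS1,trnS1
trnS1,trnS1(AGN)
trnS1,trnS(AGN)
trnS2,trnS2
trnS2,trnS2(UCN)
trnS2,trnS(UCN)
trnT,trnT
trnW,trnW
trnY,trnY
trnV,trnV
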