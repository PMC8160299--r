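# version: gpcrome-snapshot-2026.1
# Curated GPCR and GPCR-signaling gene catalog (frozen snapshot).
# Columns: species,symbol,aliases,family,category,protein_name,ortholog
# Receptors carry a GRAFS family; signaling molecules use family 'none'.
# 'ortholog' is an explicit cross-species override; blank = map by
# case-normalized symbol equality. Coverage: microglia core signature genes,
# genes prominent in the microglia GPCRome literature, major signaling
# mediators, and padding across all five GRAFS families. Not a complete
# IUPHAR snapshot.
species,symbol,aliases,family,category,protein_name,ortholog
human,CX3CR1,GPR13;CMKBRL1,rhodopsin,gpcr,CX3CR1,
human,GPR34,,rhodopsin,gpcr,GPR34,
human,GPR183,EBI2,rhodopsin,gpcr,GPR183,
human,P2RY12,P2Y12;ADPG-R,rhodopsin,gpcr,P2Y12,
human,P2RY13,GPR86,rhodopsin,gpcr,P2Y13,
human,ADGRG1,GPR56;TM7XN1,adhesion,gpcr,GPR56,
human,ADORA3,A3AR,rhodopsin,gpcr,A3 receptor,
human,ADRB2,ADRB2R;B2AR,rhodopsin,gpcr,beta-2 adrenoceptor,
human,CCR1,CMKBR1;CKR1,rhodopsin,gpcr,CCR1,
human,C3AR1,AZ3B;C3R1,rhodopsin,gpcr,C3a receptor,
human,C5AR1,CD88;C5R1,rhodopsin,gpcr,C5a receptor,
human,LPAR5,GPR92,rhodopsin,gpcr,LPA5,
human,LPAR6,P2RY9;P2Y5,rhodopsin,gpcr,LPA6,
human,PTAFR,PAFR,rhodopsin,gpcr,PAF receptor,
human,FPR1,FPR,rhodopsin,gpcr,FPR1,
human,CXCR4,CD184;FUSIN;LESTR,rhodopsin,gpcr,CXCR4,
human,PTGER4,EP4,rhodopsin,gpcr,EP4 receptor,
human,ADGRE1,EMR1,adhesion,gpcr,EMR1,
human,ADGRE5,CD97,adhesion,gpcr,CD97,
human,ADGRB1,BAI1,adhesion,gpcr,BAI1,
human,CCR6,CKRL3;GPR29,rhodopsin,gpcr,CCR6,
human,GPR84,EX33,rhodopsin,gpcr,GPR84,
human,GPR146,PGR8,rhodopsin,gpcr,GPR146,
human,ACKR3,CXCR7;RDC1,rhodopsin,gpcr,ACKR3,
human,ADORA1,A1AR,rhodopsin,gpcr,A1 receptor,
human,S1PR1,EDG1,rhodopsin,gpcr,S1P1,
human,P2RY6,,rhodopsin,gpcr,P2Y6,
human,CNR1,CB1,rhodopsin,gpcr,CB1 receptor,
human,P2RY8,P2Y8,rhodopsin,gpcr,P2Y8,
human,MRGPRX1,MRGX1,rhodopsin,gpcr,MRGX1,
human,MRGPRX2,MRGX2,rhodopsin,gpcr,MRGX2,Mrgprb2
human,GRM1,MGLUR1,glutamate,gpcr,mGlu1,
human,GRM3,MGLUR3,glutamate,gpcr,mGlu3,
human,GRM5,MGLUR5,glutamate,gpcr,mGlu5,
human,CASR,CAR,glutamate,gpcr,CaS receptor,
human,VIPR1,VPAC1,secretin,gpcr,VPAC1,
human,SCTR,SR,secretin,gpcr,secretin receptor,
human,CALCRL,CRLR,secretin,gpcr,CLR,
human,FZD1,,frizzled,gpcr,FZD1,
human,FZD4,EVR1,frizzled,gpcr,FZD4,
human,FZD7,,frizzled,gpcr,FZD7,
human,SMO,SMOH,frizzled,gpcr,Smoothened,
human,GNAI2,GIP,none,g_protein,G-alpha-i2,
human,GNAS,GNAS1,none,g_protein,G-alpha-s,
human,GNA13,,none,g_protein,G-alpha-13,
human,GNA12,,none,g_protein,G-alpha-12,
human,GNAQ,GAQ,none,g_protein,G-alpha-q,
human,GNA15,GNA16,none,g_protein,G-alpha-15,
human,GRK2,ADRBK1;BARK1,none,grk,GRK2,
human,GRK5,,none,grk,GRK5,
human,ARRB1,ARR1,none,arrestin,beta-arrestin-1,
human,ARRB2,ARR2,none,arrestin,beta-arrestin-2,
mouse,Cx3cr1,,rhodopsin,gpcr,CX3CR1,
mouse,Gpr34,,rhodopsin,gpcr,GPR34,
mouse,Gpr183,Ebi2,rhodopsin,gpcr,GPR183,
mouse,P2ry12,,rhodopsin,gpcr,P2Y12,
mouse,P2ry13,,rhodopsin,gpcr,P2Y13,
mouse,Adgrg1,Gpr56,adhesion,gpcr,GPR56,
mouse,Adora3,,rhodopsin,gpcr,A3 receptor,
mouse,Adrb2,,rhodopsin,gpcr,beta-2 adrenoceptor,
mouse,Ccr1,,rhodopsin,gpcr,CCR1,
mouse,C3ar1,,rhodopsin,gpcr,C3a receptor,
mouse,C5ar1,,rhodopsin,gpcr,C5a receptor,
mouse,Lpar5,Gpr92,rhodopsin,gpcr,LPA5,
mouse,Lpar6,P2ry9,rhodopsin,gpcr,LPA6,
mouse,Ptafr,,rhodopsin,gpcr,PAF receptor,
mouse,Fpr1,,rhodopsin,gpcr,FPR1,
mouse,Cxcr4,,rhodopsin,gpcr,CXCR4,
mouse,Ptger4,,rhodopsin,gpcr,EP4 receptor,
mouse,Adgre1,Emr1,adhesion,gpcr,F4/80,
mouse,Adgre5,Cd97,adhesion,gpcr,CD97,
mouse,Adgrb1,Bai1,adhesion,gpcr,BAI1,
mouse,Ccr6,,rhodopsin,gpcr,CCR6,
mouse,Gpr84,,rhodopsin,gpcr,GPR84,
mouse,Gpr146,,rhodopsin,gpcr,GPR146,
mouse,Ackr3,Cxcr7,rhodopsin,gpcr,ACKR3,
mouse,Adora1,,rhodopsin,gpcr,A1 receptor,
mouse,S1pr1,Edg1,rhodopsin,gpcr,S1P1,
mouse,P2ry6,,rhodopsin,gpcr,P2Y6,
mouse,Cnr1,,rhodopsin,gpcr,CB1 receptor,
mouse,Mrgprb2,,rhodopsin,gpcr,MRGPRB2,MRGPRX2
mouse,Gpr33,,rhodopsin,gpcr,GPR33,
mouse,Grm1,,glutamate,gpcr,mGlu1,
mouse,Grm3,,glutamate,gpcr,mGlu3,
mouse,Grm5,,glutamate,gpcr,mGlu5,
mouse,Casr,,glutamate,gpcr,CaS receptor,
mouse,Vipr1,,secretin,gpcr,VPAC1,
mouse,Sctr,,secretin,gpcr,secretin receptor,
mouse,Calcrl,,secretin,gpcr,CLR,
mouse,Fzd1,,frizzled,gpcr,FZD1,
mouse,Fzd4,,frizzled,gpcr,FZD4,
mouse,Fzd7,,frizzled,gpcr,FZD7,
mouse,Smo,,frizzled,gpcr,Smoothened,
mouse,Gnai2,,none,g_protein,G-alpha-i2,
mouse,Gnas,,none,g_protein,G-alpha-s,
mouse,Gna13,,none,g_protein,G-alpha-13,
mouse,Gna12,,none,g_protein,G-alpha-12,
mouse,Gnaq,,none,g_protein,G-alpha-q,
mouse,Gna15,,none,g_protein,G-alpha-15,
mouse,Grk2,Adrbk1,none,grk,GRK2,
mouse,Grk5,,none,grk,GRK5,
mouse,Arrb1,,none,arrestin,beta-arrestin-1,
mouse,Arrb2,,none,arrestin,beta-arrestin-2,
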