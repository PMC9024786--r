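subject_id,sex,age,phenotype,variant1_cdna,variant1_protein,variant2_cdna,variant2_protein,axial_length_od,axial_length_os,bcva_od,bcva_os,sibling_group
S19,F,33,NSRP,c.11864G>A,p.Trp3955*,c.13335_13347delinsCTTG,p.Glu4445_Ser4449delinsAspLeu,23.88,23.84,0.80,0.63,
S21,M,55,USH2,c.100C>T,p.Arg34*,c.926C>T,p.Pro309Leu,24.07,23.84,0.50,0.63,
S23,M,55,USH2,c.8834G>A,p.Trp2945*,c.2299delG,p.Glu767Serfs21*,24.24,24.25,0.80,0.63,
S24,F,55,USH2,c.4821G>A,p.Trp1607*,c.1859G>T,p.Cys620Phe,22.27,22.16,0.80,1.00,
S31,M,53,USH2,c.4474G>T,p.Glu1492*,c.11047+1G>A,Deep intronic variant,23.32,23.26,0.33,0.40,
S33,F,38,USH2,c.6862G>T,p.Glu2288*,c.7595-2144A>G,Deep intronic variant,25.36,24.98,0.40,0.63,
S39,M,30,USH2,c.187C>T,p.Arg63*,c.4645C>T,p.Arg1549*,22.12,22.20,0.63,0.63,
S40,F,54,NSRP,c.8981G>A,p.Trp2994*,c.13274C>T,p.Thr4425Met,23.37,23.21,1.00,1.00,
S43,M,38,USH2,c.1876C>T,p.Arg626*,c.2299delG,p.Glu767Serfs21*,23.04,22.97,0.40,0.50,
S47,M,19,USH2,c.163C>T,p.Gln55*,c.2299delG,p.Glu767Serfs21*,26.10,25.44,1.25,0.80,a
S48,F,20,USH2,c.3518C>A,p.Ser1173*,c.920_923dupGCCA,p.His308Glnfs16*,22.12,22.10,0.80,0.80,
S49,M,21,USH2,c.163C>T,p.Gln55*,c.2299delG,p.Glu767Serfs21*,27.09,26.77,0.80,1.00,a
S50,M,28,USH2,c.12954C>A,p.Tyr4318*,c.10488_10490del,p.Glu3496del,22.35,22.04,1.00,0.63,b
S51,F,34,USH2,c.12954C>A,p.Tyr4318*,c.10488_10490del,p.Glu3496del,24.47,24.76,1.20,0.80,b
S52,M,23,USH2,c.11065C>T,p.Arg3689*,c.7645_7661del,p.Met2549Alafs3*,23.62,23.55,1.20,1.00,
S55,F,20,USH2,c.7814C>G,p.Ser2605*,c.2299delG,p.Glu767Serfs21*,23.72,23.80,0.63,1.00,
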