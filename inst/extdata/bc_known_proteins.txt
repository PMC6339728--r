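XRCC3; RAD54L; casp8; BACH1; RAD51D; kras; ESR1; PALB2; NQO1; RAD51; RAD51C; TSG101; PPM1D; brca2; BARD1; BRCA1; PHB; AKT1; TP53; PIK3CA; RB1CC1; HMMR; NQO2; cds1; SLC22A18; ATM; BRIP1; CDH1
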