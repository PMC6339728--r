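RAD54L; PTPN12; EP300; DLC1; CTNNB1; AURKA; MSH6; TGFBR2; BUB1B; SMAD7; CCND1; SRC; PTPRJ; PLA2G2A; POLD1; BRAF; BUB1; MLH3; MLH1; FLCN; BAX; MSH2; APC; RAD54B; GALNT12; CHEK2P1; AKT1; TP53; FGFR3; PIK3CA; PMS2; NRAS; cds1; AXIN2; MUTYH; MCC; TLR2; DCC; ODC1
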