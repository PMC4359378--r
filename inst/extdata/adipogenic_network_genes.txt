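Pparg
Cebpa
Cebpb
Cebpd
Zeb1
Ebf1
Ebf2
Zfp423
Zfp521
Klf4
Klf5
Klf15
Egr2
Stat5a
Stat5b
Srebf1
Rxra
Nr3c1
Creb1
Xbp1
Gata2
Gata3
Wnt10b
Ctnnb1
Dlk1
Foxo1
Foxa2
Irs1
Irs2
Insr
Adipoq
Fabp4
Lep
Lpl
Plin1
Retn
Slc2a4
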