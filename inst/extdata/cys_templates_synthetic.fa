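>cysI_syn|cys|I
CFQGCTVMCDPRCENKCLWLCLAACDVDCQVMCFTNCPYG
>cysII_syn|cys|II
CRTVCWWLCGQLCAHDCFPGCIWPCHSKCELVCVMGCLNK
>cysIII_syn|cys|III
CIATCEKICGERCLRRCWTECNMDCYETCRLICTWHCDNV
>cysIV_syn|cys|IV
CILACRFSCWGQCVWPCVITCFMNCHTYCGWTCTSPCRVQ
>cysV_syn|cys|V
CDWKCMRPCDSQCQNRCYQLCWQECIDGCRTRCPYKCHGN
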