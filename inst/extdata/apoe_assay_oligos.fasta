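>e2-Forward reaction=E2 role=FORWARD
GCGGACATGGAGGACGTGT
>e2-Reverse reaction=E2 role=REVERSE
CCTGGTACACTGCCAGGCA
>e3-Forward reaction=E3 role=FORWARD
CGGACATGGAGGACGTGT
>e3-Reverse reaction=E3 role=REVERSE
CTGGTACACTGCCAGGCG
>e4-Forward reaction=E4 role=FORWARD
CGGACATGGAGGACGTGC
>e4-Reverse reaction=E4 role=REVERSE
CTGGTACACTGCCAGGCG
>APOE-probe reaction=APOE role=PROBE reporter=FAM quencher=BHQ1
CAGCTCCTCGGTGCTCTGGC
>ACTB-Forward reaction=ACTB role=FORWARD
GACGTGGACATCCGCAAAGAC
>ACTB-Reverse reaction=ACTB role=REVERSE
CAGGTCAGCTCAGGCAGGAA
>ACTB-probe reaction=ACTB role=PROBE reporter=HEX quencher=BHQ1
TGCTGTCTGGCGGCACCACCATGTACC
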