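>E2
ATTGCAACGTGGATCCTTAGGCGGACATGGAGGACGTGTCATTGGATCAAGTCCCAGCTCCTCGGTGCTC
TGGCGTTAACCTGATCGGATGCCTGGCAGTGTACCAGGCCATGAATTCGGTACGTTAA
>E3
ATTGCAACGTGGATCCTTAGGCGGACATGGAGGACGTGTCATTGGATCAAGTCCCAGCTCCTCGGTGCTC
TGGCGTTAACCTGATCGGACGCCTGGCAGTGTACCAGGCCATGAATTCGGTACGTTAA
>E4
ATTGCAACGTGGATCCTTAGGCGGACATGGAGGACGTGCCATTGGATCAAGTCCCAGCTCCTCGGTGCTC
TGGCGTTAACCTGATCGGACGCCTGGCAGTGTACCAGGCCATGAATTCGGTACGTTAA
>ACTB
ATTGCAACGTGGATCCTTAGGACGTGGACATCCGCAAAGACCATTGGATCAAGTCCTGCTGTCTGGCGGC
ACCACCATGTACCGTTAACCTGATCGGATTCCTGCCTGAGCTGACCTGCCATGAATTCGGTACGTTAA
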