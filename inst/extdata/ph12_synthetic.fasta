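>PhtRNA-Thr-CGU
GCCCGAGUGCCCGCUUUGUCCCCGGGGACGGGGUCGUGGCCCGUCAGGUCGCGUUCCCGU
CGCGACUCGGGCUCCA
>PhtRNA-Thr-GGU
GCCGGUCUACCCAUGGCGAAGUUGGGAAGGGCCUGGUAUGCCCUUCGCCGCCUUUCGCUU
AGGCGGACCGGCUCCA
>PhtRNA-Thr-UGU
GCCCGGCUGUCCGAGUUAGCUCCGGACGUAUCGUUGUAUGAUACGUCCCGUGAUUCAAGA
UCACGGCCGGGCUCCA
>PhtRNA-Cys-GCA
GCCAACUUAGCCGCUGUACGGUCGGCUGAGGGGUGCAGGCCCUCGGAAGCUUCUUCCUCG
GAAGCAGUUGGCUCCA
>PhtRNA-Ser-UGA
GCCGCCCUGGCCUGAGAAGUCUAGGCAAUCGCUUUGAAUGCGAUUACUCACUGGCUCAGC
GGCUUCCAGUGCCGCGGGCGGCGCCA
>PhtRNA-Ser-CGA
GCCCCGCUAGCCGUCGGGCCCACGGCAGGGCGAUCGAAGCGCCCAACGUGUCUAGAUUCC
CCGUUCCCCGCGGGGGCGGGGCGCCA
>PhtRNA-Ser-GGA
GCCCGCCUAGCCGAGUCCUCUCCGGCCCCUGCUUGGAGGGCAGGAACCGACGUCUGCUUC
ACUUUCGCUAAGUGAGGCGGGCGCCA
>PhtRNA-Ser-GCU
GCCCUCCUAGCCGGGCGUUGCCCGGCGCACCUAUGCUGGAGGUGAGAAUGCCUACUGUCG
AACUUCGCGAGUUCGGGAGGGCGCCA
>PhtRNA-Asn-GUU
GCCGCACUACCCGGCUUGGUCUCGGGGUCGCCGUGUUGGGGCGACUGACUAGGUUCGUUA
CCUAGGUGCGGCGCCA
>PhtRNA-Asp-GUC
GCCGCGGUGGCCCCGAUCGACGGGGCGCCGUGUUGUCGGCACGGAUCCGCGAGUUCUCUC
CUCGCCCGCGGCGCCA
>PhtRNA-Arg-GCG
GCCCACCUAGCCCUAUAUUAGUGGGCCCGACUUUGCGGGAGUCGAGUACGGGCUUCUGAU
GCCCGGGUGGGCGCCA
>PhtRNA-Phe-GAA
GGCGGCGUAUCCCCCGUGUGACGGGAACGGCUGUGAAGGAGCCGCGGCUCGCGUUCAUCC
CGCGACGCCGCCACCA
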