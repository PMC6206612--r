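>SSU_tail_1
CCTATAATCTACCCGCAGAGGACA-GTGGCCGGACTACGCTC-GCATTGTTATGTAAATCAT
>SSU_tail_2
CCTATCATCTACCCGCAGAGGACA-GTGGCCGGGCTACGCTC-GCATTGTTATGTAAATCAT
>SSU_tail_3
CCTATAATCTACCCGCAGAGGACA-GTTGCCGGGCTACGCTC-GCACTGTTATGTAAATCAT
>SSU_tail_4
CCTATAATCTACCCGCAGAGGACAAGTGGCCTGGCTACGCTCAGCATTGTTATGTAAATCAT
>SSU_tail_5
CCTATTATCTACCCGCAGAGGACA-GTGGCCGGGCTACGCTC-GCATTGTTATGTAAATCAT
>SSU_tail_6
CCTATAATCTACCCGCAGAGGACA-GTGGCCGGGCTACGCTC-GCATTGTTATGTAAATCAT
>SSU_tail_7
CCTATAATCTACCCGCAGAGGACA-GTGGCCGGGCTATGCTGGGCATTGTTATGTAAATCAT
>SSU_tail_8
CCTATAATCTACCCGCAGAGGACACGTGGCCGAGCTACGCTC-GCATTGTTATGTAAATCAT
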