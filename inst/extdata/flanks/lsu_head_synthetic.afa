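>LSU_head_1
TGTACACTCTTATTGATC-GGGATACTTTAGATAGGTGCAAGGGACACC-ACGTGGCTATTC
>LSU_head_2
TGTTCACTCTTATTGATC-GGGATAATTTAGATAGTTGCAAGGGATTCC-ACGTGTCTATTG
>LSU_head_3
TGTGCACTCTTATTGATCAGGGATCCTTTAGATAGTTGCAAGGGACTCCCACGTGGCTATTC
>LSU_head_4
TGTCCACTCTTATTGATC-GGGATACTTAAGATCGTTGCAAGTGACTGC-ACGTGGCGATTC
>LSU_head_5
TGTACACTCTTATTGATCCGGGATACTTTAGATAGTTGCAAGGGCCTCC-ACGTTGCTATTC
>LSU_head_6
TGTACACTCTTATTGATC-GGGATACTTTAGATATTTGCAAGGGACTCC-ACGTGGCTATTC
>LSU_head_7
TGTACACTCTTATTGATC-GGGATACTTTAGATAGTTGTAAGGGACTCCTAAGTGGCTATTC
>LSU_head_8
TGTACACCCTTATTGCTC-GGGATACTTTAGATAGTTGCAAGGGACTCC-ACGTGGCTATTC
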