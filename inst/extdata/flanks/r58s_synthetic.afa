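>R5.8S_1
CCTGGCAATCTGCACACTCCGTATTTATGCGCAGCTAAAC-GCGCTTTTGTTAATGAGTTGCGGATGTAGCAAGCTATTTATATAGCTTGAGTGCTCCTCTCATAGCGTCTATGACCTGCCCTGCCGTAGGATATGTGCCAA
>R5.8S_2
CCTGGCAATCGGCACACTCCGTATTTATGCGATGCTAAAC-GCGCTTTTGTTAATGAGTTGCGGATGTAGCATGCTATTTAT-TAGCGTGAGTGCTCCTCTCATAGCGTCTATGACCTGCACTGCCGCAGGATATGTGCCAA
>R5.8S_3
CCTGGCAATCTGCTCACTCCGTATTTATGCGCAGCTAAAC-GCGCTTTTGTTAATGAGGTGCGGATGTAGCATGCTATTTAT-TAGCTTGAGTGCTCCTCTCATAGCGTCAATGACCTGCCCTGCCGCAGGATATCTGCCGA
>R5.8S_4
CGTGGCATTCTGCACACTCCGTATTTATGCGCAGCTAAAC-GCGCTTTTGTTAATGAGGTGCGGATGTAGCATGCTATTTAT-TAGCTTGATTGCTCCTCTCATAGCGTCTATGACCTGCCCTGCCGCAGGATATGTGACAA
>R5.8S_5
CCTGGCAATCTGCACACTCCGTTTTTATGCGCAGATAAAC-GCGCTTTTGTTAATGAGTTGTGGATGTAGCATGCTATTTATATAGCTTGAGTGCTCCTCTCATAGCGTCTATGACTTGCCCTGCCGCAGGTTATGTGCCAA
>R5.8S_6
TCTGGCAATCTGCACACTCCGTATTTAGGCGCAGCTAAACCGCGCTTTTGTTAATGAGTTGCGGATGCAGCATGCTATTTAT-GAGCTCGAGTGCTCCTCTCATAGCGTCTGTGACCTGCCAAGCCGCAGGATATGTGCCAA
>R5.8S_7
CCGGGCAATCTGCACACTCCGTATTTATGCGCAGCTAAAC-GCCCTTTTGTTAATGAGTTGCGCATGTAGCATGCTATTTAT-TAGCTTGAGTGCTCCTCTCATAGCGTCTATGACCTGCCCTGCGGCAGGATATGTGCCAA
>R5.8S_8
CCTGGCAATCTGCACACTCCGTGTTTATGCGCAGCTAAACCGCGCTTTTGTTAATGAGTTGCGGATGTAGCATGCTATTTAT-TAGCTTGAGTGCTCCTCTCATAGCGTCTATGACCTGCCCTGCCGCAGGATATGTGCCAA
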