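>A1
ATGCGTTCACCTTCTGCTGCCGCGACACTCTCGACGGCGTCAGCCACCCCGCGAGGGGTAGCCCGGGCAGGTACACTACTTCTCGCAGTGGTGGTGCTGGTGACACGAGTCTCCACAACCGCGCGGACCGCGGGACGGGGCGGCGGCGCAGGCGCGGCTGCGCTGGCCCCAGTTGGTGCACCATCGCGTCGCGTCTCGCTGGGGCCGGTTCTATCTCCCCGTGGATCACTCTCCGGTCTGGCCGTAGTCGCCGTAGTAGCAGGAGCTTCGGGGGCCACTGTGTCTCTACGCCTCGTCCGG
>A2
ATGCGTTCACCTTCTGCTGCCGCGACACTGTCGACGGCGTCAGCCACCCCGCGAGGGGTTGCCCGGGCAGGTACACTACTTCTCGCAGTCGTGGTGCTGGTGACACGAGTCTCCACAACGGCGCGGACCGCGGGACGGGGCGGCGGCGCTGGCGCGGCTGCGCTGGCCCCAGTTGGTGCTCCATCGCGTCGCGTCTCGCTGGGGCCGGTACTATCTCCCCGTGGATCACTCTCCGGTCTCGCCGTAGTCGCCGTAGTAGCAGGAGCTTCCGGGGCCACTGTGTCTCTACGCCTCGTCCGG
>A3
ATGCGTTCACCTTCTGCTGCCGCGACACTCTCGACGGCGTCAGCCACCCCGCGAGGGGTAGCGGCGTCTACGGGCCCGGGGGTGCTCACGCGTCTAGCACGGTCTGGACCAGCGCCACTACTGGCCTCCGGTTCCGGGGCGCGACCCGCCTCTGCGGTTACTGCTGGTCTAACCCTCTCAGGCCCTGGATCGTCAACTCTCCGACTCACATCACCGGCAGCCGGCCTTCGGGTCGTGCCCACGCTTGCTGGCCGGACTCTCGTAGCCTCTGCACGGCTAGCCCTTCGGGTATCTACCCCT
>B1
ATGGTAACTCCCGTAACGCCAGTGGTAGGTGGAGCGGGGGCTGGGCGCACAACGGTCCCACTTACCACTGTCTCTGCCCCTCCACTACTCGCACGTCTCGCCGGAGCTCTGGGGTCCACAACTCTTACAGCAGCTCTTGTTGGGCTGCGACCCCTGTCGCGTGCCCTCGGGCTTGTGGGGACTGTTTCCGTCCTGTCACTTGTATCTCCCTCCACGGGACGTACGCGCGGAACCCTCCGCCGTACTACCCCTACCTCTGTCCGATCGGGTCTGGGAGGAACACCCGGAGTAGTCGCTCTA
>B2
ATGCGTTCACCTTCTGCTGCCGCGACACTCTCGACGGCGTCAGCCACCCCGCGAGGGGTAGCCCGGGCAGGTACACTACTTCTCGCAGTCGTGGTGCTGGTGACACGAGTCTCCACAACCGCGCGGACCGCGGGACGGGGCGGCGGCGCAGGCGCGGCTGCGCTGGCCCCAGTTGGTGCTCCATCGCGTCGCGTCTCGCTGGGGCCGGTTCTATCTCCCCGTGGATCACTCTCCGGTCTGGCCGTAGTCGCCGTAGTAGCAGGAGCTTCGGGGGCCACTGTGTCTCTACGCCTCGTCCGG
>B3
ATGCGTTCACCTTCTGCTGCCGCGACACTCTCGACGGCGTCAGCCACCCCGCGAGGGGTAGCCCGGGCAGGTACACTACTTCTCGCAGTGGTGGTGCTGGTGACACGAGTCTCCACAACGGCGCGGACCGCGGGACGGGGCGGCGGCGCAGGCGCGGCTGCGCTGGCCCCAGTTGGTGCACCATCGCGTCGCGTCTCGCTGGGGCCGGTTCTATCTCCCCGTGGATCACTCTCCGGTCTCGCCGTAGTCGCCGTAGTAGCAGGAGCTTCGGGGGCCACTGTGTCTCTACGCCTCGTCCGG
>C1
ATGCTATCAGTAACTCTCGTCCTGCGCCCGGTGGGTCGAGGTCTTGCACGAGCGGCCGCCGTGGTCCGTACCGCAGGCCTACGAGCCCGGGTTGCGCTAGTTTCGGCACTGACTACTACTTCTGGGCCCGCAGGACTGGCCCGCTCGACAGTGCCGGTGGCTCTTCGGGCTCTTGGTTCCGGTCTCCGCGCGCTTTCCTCGCTCCTCCGTGGGTCCGGACTGACGACCCGTGCACGCCCTCCCCTCGTACGGCCTGCGGGGACCCTCGTATCACCCCGCGCGGTGTCCGGCACAGCTCGTCTTACTCGTACTCCCGTAACCTCACCGCGCCCGGTTACTCTACGGCTACCACGCTCGCGTCTGGGCCGCCTGCGCGCGCTTGGTTCTACAGGTCTCGGTGCCCCTACGCCGCTAGCGCGAGTTCTCACGGGACCCGCTGCCGGTGTAGCTTCCGTCGCCGCAGCGCTAACGCTGCCCGGACTTCTTTCGCCGACTCTAACGGTCCCTTCCGGCCCTGTACCCACAGCAACTACAACAACCCGGCTCCCACTCCGCCTAACCCCATCTCCAGCGACCACCGCTGGTTCGCGAACCCCGGCG
>C2
ATGGCACTACGTGGAGCTGCCCTTCCGGCACTCCTCGGCGCTGTCCCAGTGTCTTCAGTGCTCGGACTGCTAGTGGGCGCGCGTACAGTACGTCCACGCGGGCCAGTCCTTCTCGGGCCACCTGCCTCTGTCTCCCCAGGCGGCACGGCCGTGCCTGGGTCGCGAGCAACGTCGTCAACCGTATCTACTGCTGTCTCTCCCTCTCGAGTCGGTTCCTCCGGTCTTCCCGTCGCAGCACGAACGGTTTCCGGTCGACCCGGGGTACGAACGGGCCCTGCAGTTTCGTCGCCCTCCCTTGTCGGAGTTACGGTTGGACCTGGCCGAGTGCTCTCCGTGACTTCGCCCCCCGCACGGGCATCTGTTCCGGCCCGGGTGCCAGCGGGTGGAGCGGTGGGAGGGGGACCTTCGACCCGGTCTGTGACACTACCGGCGTCTGCGTCACGGGCCCGTCTTACTGCTTCCCCGCCGGCTACTGTACGTTCCCGGTCAGCCTCACGGCGCGCAACCTCGGGGGGGGGCCGCGCCGCGACGCGATCACTCGCTTCTGTAACGCTGCTACGTCCTACAGCTCTCGCTGCTACAGCCGCGGTGGCTCTATCT
>C3
ATGTCGCCTGTGGTCCTGGCTGCCGCGGGATCACTGGTCGCGGCAGTTCCTCTGTCACCA
>C4
ATGGGCGCATCGCGCGGCCGTCGACCACGTCTTGCTCCACGATCAGCAACTGTTGCGCCGTCGCGTGCCGCTCGCCCCTCGCTCGCAGGTCGACGATCTGCGCTTGTAGCTTCCACTGCACCGGGGGTGGGCCTCCTTACTTCTCTACTT
>D1
ATGGTTCGCGCCGTTCTCGGGGGACTGCTCTCTGGTTCGCCTACCGGTCGTGGGGTTGTCGCTACCCCTCCAGCTGCCACGCTGCGGGCAGTCGTTTCAGCGACAGGACGAGCGGGACTGCGCCGTACGACACCTCCACTCGTTCCCGTAGCTACACCTGTTGTCGGCTCGGCCACTGCATCGTCGCTCCGGGCATCCTCCGCACCGCCGTCCCCAACCGTCACCTCAGCGCGAGCAGTGCCAGGTGGCCCACGCGGTCTAGTGGTGGCCGCCGGGACTGTACGTGTAGGGCTGGGTCGG
>D2
ATGGTTCGCGCGGTTCTCGGGGGACTGCTGTCTGGTTCGCCTACCGGACGTGGGGTTGTCGCTACGCCTCCAGCTGCCACGCTCCGGGCAGTCGTTTCAGCCACAGGACGAGCGGGACTCCGCCGTACGACACCTCCTCTCGTTCCCGTAGCTACTCCTGTTGTCGGCTCGGCGACTGCATCGTCGCTCCGCGCATCCTCCGCACCGCCCTCCCCAACCGTCACCTCTGCGCGAGCAGTGCCAGGAGGCCCACGCGGTCTAGTCGTGGCCGCCGGGACTGTACGTGTAGGGCTGGGTCGG
>E1
ATGCCTCTGTCAGGGACGACTCCCTCACTAACCCGGCGGGTTTCACCCGCAGGACGGCCTACCCTTCCGGTGCTTGTGACTCGACCGGCCCTTGGGCGCTCGCCAACACCGCTTGCGGTTGGTCTTGTTACTACGGGCACCTCCCGTTCTACCGTTGCCTCTTCACGATCTGTACCACGGCGTCTCTCTCCGGCT
>E2
ATGGCGGGTGGGACGGCCGGGCCCTCCCCGTCACTGGCACTAGTTTCGTCCCTAGTAGTCGGGGCGCTGACCGGGCTAGCCGTGCCCCGCCTTCCCCCACCTGTTCCGCGGCTGGGATCTACTCCTGCAGGTGGGCTCACCCTGTCAGTAACAGTTCCTGTCACGACGGGGGGTTCCGTATCGGCCACTCTTGCGCCACTGACTTCTCTGTCGCGTGGTGTGGGGTCTCCCACTCGAACGCTCCGGGGTCCTCGGCCTACCCCTCTACGTCGAACAACTGGTGCGCGACGTGCGGCACGG
>A1_utr5
GAAATGCACAAATATAGCATCTTCCGAGAACATAATTGAAAAACGTCCTAACTTCATCTTATGAAGTGATAAAATGAGAACGTCTATTACGAAAAGTTTTCAGAATAATGTAGGATTTGT
>B1_utr5
GAGTACACACAACAGGGTTGCTCATTTTTGTCACTTCACA
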