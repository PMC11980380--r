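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
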