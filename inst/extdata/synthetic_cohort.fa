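>seq001_polyprotein
CAGGCCCAGGATCCTATATTGTATGGTGCAACGCTATTCACCCCGGAAGTGCTAAATGTGTTCGGAAAGTTAGCAGGGACAGAAGGTCGCGGTGATCAACCCATCCTGGATGTAGACAAACACAGTGCTCCAAATAATTATGCGGATAATCACAAAACCACGCTGGACCTTGGGAACGTTGTCCACGAAGACGCCGTGAGCCAGTTTCAAACAAAATGTCCCTACCCTGAAACACCAGCACATGTTATTGAAAATCAGCCGTTCGGAGCAAATGGGGAAGCCTTCGCATGCTTTCTTGTCTTCCTCGTATCTTGCGAATATCTAGGACGAAGTTTCACAGTATATCACAGGGTACCCGAGGTGCCCGTGATATATGGTCCTAGAACGTTCTGTAAGACGGGGACCAAAGCTAATATTCCTCCTAAATTTATTCAATACCAATATTTTATTGATGATGCCGAAGTGGCAGGGAACCATGGCCAGGCGGAGTATAAACATCAGGGGCACGCGAGGTCAGTGAATAATGAATGCAGGGTCGGAAATCGCGACAATTCTGACTTTCTTGAAATTTTCTGCAATAAACTCGAATACCCAAGTCCCCGTTCAATACCTGTCAGTAGGGTTGAAGAAAATATCAGTAAACCAGGGCCATATGCTGACTTTCATCCCTCTTGCAGATTCAGGACAAGCGGTCCATCGGAAGAATTTGGCAATGAAGACTTCGCAGTAGGGGGTAATTTTAAGTTCCCTTAA
>seq002_polyprotein
ATTAATAGGCTTAAAGGATATGGCACCTCCAAGCCCATATTCAGGCAAAGGTATAGCCGCTGTCTACACGATACGGCTGGTGCCCGATTCTTCATTACCTACCAGACGTCAAACCGACCCCAGTCTGCATTTCCCGATTTCGTAACACAAGGCGATTGCAACGCGCTTGTTCCCTCATTTGATGCGGGGTTCCGTAGCTTTCATCCACATAGAAAGGGGGACCGACCGTCGTCGTGCGACTTCCCACCCGTATTAAAGATAGATGACTGTTCACACGAGTGCAATAATCAAAATGCTGAGGGTGTGCCCAGACGGAATGGGATACTTGAGCGCTGTTCACGCCAACGCGGCCATCCCGGGATCTTCAGACAACAGAATGGTTATGTTGAAGGTATCCGCGCTAATGCGGCCACTCTACAGAAAAAATCTCGCTGTATTCTACGAATCCACTTCACTAAAGCAATCCCGCCTCATAAGATCGGGTCACCTGATTGTACGCAGTTTAGGCTCACCGATGAGTGTGTTCCATCACTAATTAGCCGCCTAGTCGCCCACGGGGTGTACACATCCCCCTACGCTCAGACCGTTGTCCGTTATGTGCACCATGACGAAAGAAGGTATGCTGTTCAGAACGACTCATACTATAAAGTGGGATCTCAAGAACACATAGCGGCTAAGAAAATCGCTAGCCACGATAAAGGTGCATTTAATCAGGACGACGGCCAACAGTACGCGGCCGACTTTGCAAAATAA
>seq003_polyprotein
TCGCCCAGTATTGATTTTGACAAGAGACAGACCCTCGACACGGTCCCTGCGGATATAAATCAGAATGATCCAACCTATATCCAAGTTTGTCCACAGGATACAGAGCTAAATCGTCATTGCCGGATTTTTAAACAGTTTTTTCATGTTTTCATTAAGTTTAAAACCGCATATCAAGGCAATTGCAGCAGCGAAATAGTACTGACGATTAAACGGGGTGGGGGGCAGATCGTACAGGAAAGATGTTTTGCACTATCGTACTGTGTGGAAAGACAGGTCCTAAAGGATCACGTGAGATCCCACATTTGTCTAAGTGACCAGAGGACGTCGCTCTTTGCCGAGAAGTTTAAATTATTCTGTGGGCCGTGTTGTCAGTTCTTCATTTGTTGTAAACACAGCTGCGAGGCGGCCATAAACGCGTTCGGGTGCTTCTTCCTTACGGGCAGAAATCACTCCGTAGAATACTTTCAGGTCGTGGAATATCAAAATAAGGCACTACATTATGATCCGGCCCATTGCCATCTACCCGGAACCACGGCGGCTAAGAGGTTGATTACCGCACACTACTTTGACGATAAAAACAATGCTAATGTCACGATCCAGCATCATGCAATTGCCACCCGGTACATCTCAAGAAATTTTTTTGGCTATGAGTGTGCATGTCATGTTTTGTACGTGTTCGCAGGCGCCCTTAGAAAACGGAATAGACCCATTGGTCTCTGCACGAAATTTTTTTCACACGAAGAATATGAATAA
>seq004_polyprotein
GCTTTAGAATTCGTCACCGCGGCCACCATTTCAAAGTGTGCAGAATGTAATCATATCAAATTTCCCGAAAACTCCTGTAATGGGACTCAGGAGGCAAAATACCACGAGGGTAAAGCTGAAGATACTCCGTTTGGCCAAAAAGTCTTCGTTGTCGGGGGGGGGCTACACAATGAAAGAAATTCACGCAAGGATGTCGACGAAAAAGACTGCCATCAATCGAAGCAGCATGCTATTCTGAGCTTGAATGACGAACAACCTGCGAATCAGGGGTTTCCACATTTTCAGTCTCACCCCGATGGCGATAACACAAAGCATAATCTTGTTACGTCACCCCGCACCCACCCACTTTATCACGGAGGCGGCCAAGACGGGGTGGATTGCCACGTCTTTCACGTCCTGGATTCCAGGTACAAACGGCATTTCACCTATGCTGCTGCTGTGCCCTGTCAATGTTTTGATTGTGGTAACGGCCGCACCGTTAGCGTCGCATTCTGTGTTCCTATAAAGAGGGTAGTAAATCTTGAATGCATAAAACACAAAGATGTTTATCCACAATTTAATGTAGAAGGGGTTTATTCTCATCAACGGCAAACCTTCTTCGTGAGGGGCTTGTCAACTAACATTCGCCAACGCGAAGCTATAGAGGCAGTGGTACCCGATAACAGGAATTGCCAATATTTTATCTACGAAGATATACATCTTTTTGTGTACCAAATCCATTACGCCATTAAACAAAATTACTATGGTGCGTAA
>seq005_polyprotein
CGAGCTTACACCCAGTACCTGCCACTAAAAGAAGGTAACTATTTGTCATCGCTACAAACGCAGGCCGTCGCTGTCCGCCTGCAAACCAAAATCAACTGTAAAAATACTCACTGCCATCATCTAACGTTAAGATGCTTTCAGTGCCAATATTTAATCAATGATCTAGGGAAACCGGACGTTCAGACCGAAATAGTGAAATTCCCACAAATAGGCCCGCCAGACCAAGTCGGATACGGGCCTGACCACGTGGCACACCCCCATGACATAGAGATCCTTTTTGGTCGTCGCTCACAACCCTGCCACTATGAACACTTTCGGAACCCCGTCGATAACTTCCTCTACATCCAATATGTGGCTGTGGACTTTGAAGAAGTCAACCCCGGCTGCGAATATGATATACTCGCAAAAGTGAACACCACCGGGCAACGTCGGACCTGCCGCACGCTAATCCCGCACGATGTTTGCCAATACTCAGACAATCAATTCTCCTACGGAGTGGCAGAAATTCCCCAATACCGATATCATGCGGTTGTAAGTATACCAAAAAAACTAGAATGTCATTACCCCTGTATCGACGCATACAATGCTCACTCAAAATGTGGGTCAACGACTCAATTTCACAAATTAGTGGTATATAAACGAGACAAAATTAGAAAGGCGAATGACCAAGTTCACGAACCCGCTATAGTCTTCTACGAATACCTATCTAATCGCCGCCTCCCCCACATAAGCAATCACGCTAACTATCAATAA
>seq006_polyprotein
TATTCATACTACAATGCCATAGCACTCAACCAAGTGCAACGACATGTTGCGTACAACCAAAAAGATAAATTCAGTACGACGCCGCCTAGACATACGGAGGCAGTTAGTGGTGCTTACCTTCTAAGGCGCGATCTAATACGGGTGCCCAATAATTTCCAACCTGATACGACAGATTATGGTGATTTGGAGACCACCCATGATGTGTGCAGATACCTCAACTTGATTGATTCATATAATACGCAGGATCACGCTTCTGCCCCTAATCCGGGAGAAGCAATCCCTGCCGAGTGCGGGCCCACATTCTACTCTTTTGACACCTGCGACCAGTTTTCAGAAAACTTTTTAGAAGCATTTAGTGTGAACAGTCATAACTTTTTTATCATATTCTACACCATACCAAAAGAAAATGAACAACACGTCCATCATGACTTCTGTCCAAATCACACCCTACCAAGGCCGTGCCCAGGTGAAACTAATCAGACCACGAATCCCGACACCCACCTAGCCTTTTGTGAGCCATCTGAAATAAAAGATATTCCCCGCCAATACAATGCGTGCTTTGACGTCGTGAAGTCGTACGTCTATCTGTTCGATTTTAAACGCACCGACTACGACAGTGACGAGTTTCGGTGCCGCTTTAAACTCGATTGCCACCCTTACACGCAAAAACTGCATGATTATTGTAAACATCGGGGAGCTGTCGAGTATTACTGTGCTTGCGACTTCCAGTGTTACAAAGGACTTCAACAATAA
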