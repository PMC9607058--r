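codon	count
GCA	140
GCC	57
GCG	64
GCT	130
TGC	110
TGT	127
GAC	183
GAT	195
GAA	152
GAG	50
TTC	63
TTT	77
GGA	117
GGC	107
GGG	166
GGT	98
CAC	112
CAT	129
ATA	132
ATC	157
ATT	165
AAA	145
AAG	53
CTA	120
CTC	31
CTG	75
CTT	67
TTA	54
TTG	31
AAC	22
AAT	61
CCA	80
CCC	119
CCG	27
CCT	85
CAA	192
CAG	124
AGA	152
AGG	101
CGA	90
CGC	174
CGG	69
CGT	145
AGC	120
AGT	88
TCA	176
TCC	87
TCG	83
TCT	114
ACA	36
ACC	155
ACG	156
ACT	22
GTA	80
GTC	176
GTG	194
GTT	199
TAC	124
TAT	121
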