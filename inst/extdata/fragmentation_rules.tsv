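rule_id	type	formula	adduct	classes	tolerance_ppb	description
tma_loss	loss	C3H9N		PC;SM;LPC	500	neutral loss of trimethylamine from the choline head group
pchol_loss	loss	C5H14NO4P		PC;SM;LPC	500	neutral loss of the phosphocholine head group
atp_adenine_frag	fragment	C5H8O9P2	[M-H]-	nucleotide	500	triphosphate-ribose fragment after adenine loss from ATP
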