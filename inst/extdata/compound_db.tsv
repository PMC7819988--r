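id	name	formula	class	adducts_pos	adducts_neg
atp	adenosine triphosphate	C10H16N5O13P3	nucleotide		[M-H]-
adtp	adenosine tetraphosphate	C10H17N5O16P4	nucleotide		[M-H]-
cmp	cytidine monophosphate	C9H14N3O8P	nucleotide		[M-H]-
gpc	glycerophosphocholine	C8H20NO6P	GPC	[M+H]+;[M+Na]+;[M+K]+	
ip5	inositol pentakisphosphate	C6H17O21P5	other		[M-H]-
ip4	inositol tetrakisphosphate	C6H16O18P4	other		[M-H]-
prpp	phosphoribosyl pyrophosphate	C5H13O14P3	other		[M-H]-
pc_32_0	PC(32:0)	C40H80NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_34_1	PC(34:1)	C42H82NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_34_2	PC(34:2)	C42H80NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_36_1	PC(36:1)	C44H86NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_36_2	PC(36:2)	C44H84NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_36_4	PC(36:4)	C44H80NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_38_4	PC(38:4)	C46H84NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_38_6	PC(38:6)	C46H80NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
sm_d34_1	SM(d34:1)	C39H79N2O6P	SM	[M+Na]+;[M+K]+;[M+H]+	
sm_d36_1	SM(d36:1)	C41H83N2O6P	SM	[M+Na]+;[M+K]+;[M+H]+	
sm_d38_1	SM(d38:1)	C43H87N2O6P	SM	[M+Na]+;[M+K]+;[M+H]+	
sm_d40_1	SM(d40:1)	C45H91N2O6P	SM	[M+Na]+;[M+K]+;[M+H]+	
sm_d42_1	SM(d42:1)	C47H95N2O6P	SM	[M+Na]+;[M+K]+;[M+H]+	
sm_d42_2	SM(d42:2)	C47H93N2O6P	SM	[M+Na]+;[M+K]+;[M+H]+	
lpc_20_4	LysoPC(20:4)	C28H50NO7P	LPC	[M+Na]+;[M+K]+;[M+H]+	
lpc_16_0	LysoPC(16:0)	C24H50NO7P	LPC	[M+Na]+;[M+K]+;[M+H]+	
lpc_18_0	LysoPC(18:0)	C26H54NO7P	LPC	[M+Na]+;[M+K]+;[M+H]+	
lpc_18_1	LysoPC(18:1)	C26H52NO7P	LPC	[M+Na]+;[M+K]+;[M+H]+	
tg_52_2	TG(52:2)	C55H102O6	TG	[M+Na]+;[M+K]+	
tg_54_3	TG(54:3)	C57H104O6	TG	[M+Na]+;[M+K]+	
pa_34_1	PA(34:1)	C37H71O8P	PA		[M-H]-
pa_36_2	PA(36:2)	C39H73O8P	PA		[M-H]-
pa_38_4	PA(38:4)	C41H73O8P	PA		[M-H]-
pa_40_6	PA(40:6)	C43H73O8P	PA		[M-H]-
ps_36_1	PS(36:1)	C42H80NO10P	PS		[M-H]-
ps_38_4	PS(38:4)	C44H78NO10P	PS		[M-H]-
ps_40_6	PS(40:6)	C46H78NO10P	PS		[M-H]-
carnitine	carnitine	C7H15NO3	other	[M+H]+;[M+Na]+;[M+K]+	
acetylcarnitine	acetylcarnitine	C9H17NO4	other	[M+H]+;[M+Na]+;[M+K]+	
phosphocholine	phosphocholine	C5H14NO4P	other	[M+H]+;[M+Na]+;[M+K]+	
amp	adenosine monophosphate	C10H14N5O7P	nucleotide		[M-H]-
gmp	guanosine monophosphate	C10H14N5O8P	nucleotide		[M-H]-
ump	uridine monophosphate	C9H13N2O9P	nucleotide		[M-H]-
nad	nicotinamide adenine dinucleotide	C21H27N7O14P2	nucleotide		[M-H]-
glutathione	glutathione (reduced)	C10H17N3O6S	other		[M-H]-
hexose_p	hexose monophosphate	C6H13O9P	other		[M-H]-
glycerol_3p	glycerol 3-phosphate	C3H9O6P	other		[M-H]-
taurine	taurine	C2H7NO3S	other		[M-H]-
adenosine	adenosine	C10H13N5O4	nucleotide		[M-H]-
uric_acid	uric acid	C5H4N4O3	other		[M-H]-
citrate	citrate	C6H8O7	other		[M-H]-
ascorbate	ascorbate	C6H8O6	other		[M-H]-
pc_30_0	PC(30:0)	C38H76NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
pc_32_1	PC(32:1)	C40H78NO8P	PC	[M+Na]+;[M+K]+;[M+H]+	
sm_d32_1	SM(d32:1)	C37H75N2O6P	SM	[M+Na]+;[M+K]+;[M+H]+	
lpc_22_6	LysoPC(22:6)	C30H50NO7P	LPC	[M+Na]+;[M+K]+;[M+H]+	
pe_34_1	PE(34:1)	C39H76NO8P	other	[M+H]+;[M+Na]+;[M+K]+	
pe_36_2	PE(36:2)	C41H78NO8P	other	[M+H]+;[M+Na]+;[M+K]+	
pi_34_1	PI(34:1)	C43H81O13P	other		[M-H]-
pg_34_1	PG(34:1)	C40H77O10P	other		[M-H]-
pa_32_0	PA(32:0)	C35H69O8P	PA		[M-H]-
ps_34_1	PS(34:1)	C40H76NO10P	PS		[M-H]-
dhb	2,5-dihydroxybenzoic acid (matrix)	C7H6O4	other	[M+H]+;[M+Na]+	
dhb_cluster2	DHB matrix cluster 2	C14H8O6	other	[M+H]+	
dhb_cluster3	DHB matrix cluster 3	C21H12O9	other	[M+H]+	
aminoacridine	9-aminoacridine (matrix)	C13H10N2	other		[M-H]-
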