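mode	name	formula	adduct	mz_ref
positive	DHB matrix	C7H6O4	[M+H]+	155.033885
positive	carnitine	C7H15NO3	[M+H]+	162.112470
positive	DHB matrix sodiated	C7H6O4	[M+Na]+	177.015829
positive	phosphocholine	C5H14NO4P	[M+H]+	184.073321
positive	acetylcarnitine	C9H17NO4	[M+H]+	204.123034
positive	DHB matrix cluster 2	C14H8O6	[M+H]+	273.039364
positive	DHB matrix cluster 3	C21H12O9	[M+H]+	409.055408
positive	PC(32:0)	C40H80NO8P	[M+H]+	734.569432
positive	PC(34:1) potassiated	C42H82NO8P	[M+K]+	798.540964
negative	dipeptide marker	C17H26N6O6	[M-H]-	409.184106
negative	adenosine diphosphate	C10H15N5O10P2	[M-H]-	426.022139
negative	adenosine triphosphate	C10H16N5O13P3	[M-H]-	505.988470
negative	tripeptide marker	C23H39N7O7	[M-H]-	524.283820
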