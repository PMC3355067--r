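id	equation	gpr	subsystem	is_exchange
EX_glc	glc[e] <=>		exchange	TRUE
GLCt	glc[e] => glc[c]	(hk1 and hk2) or glut1	transport	FALSE
GLYC	glc[c] => 2 lac[c]	pfk or pk	glycolysis	FALSE
LACt	lac[c] => lac[e]	mct1	transport	FALSE
EX_lac	lac[e] <=>		exchange	TRUE
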