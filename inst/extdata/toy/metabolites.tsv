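id	name	compartment	formula
glc[e]	glucose	extracellular	C6H12O6
glc[c]	glucose	cytosol	C6H12O6
lac[c]	lactate	cytosol	C3H6O3
lac[e]	lactate	extracellular	C3H6O3
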