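gene	tissue	hpa_level	expression_signal
glut1	liver	high	120
glut1	brain	medium	80
pfk	liver	medium	60
pfk	brain	absent	10
pk	liver	absent	5
pk	brain	low	30
mct1	liver		200
mct1	brain		20
hk1	liver	low	15
hk2	brain	low	12
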