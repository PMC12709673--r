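mask	delta_isc
a99	2.41
a100	0.94
a101	1.87
b98	1.32
b99	0.21
b100	0.58
alpha	3.12
beta	1.18
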