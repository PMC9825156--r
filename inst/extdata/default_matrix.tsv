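	A	C	G	T
A	-3	-2	-3	2
C	-2	-2	3	-2
G	-3	3	-3	1
T	2	-2	1	-2
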