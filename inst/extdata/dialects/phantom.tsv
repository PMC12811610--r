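name	code
presubiculum	1
subiculum	2
CA1	3
CA2	4
CA3	5
CA4	6
DG	7
molecular_layer	8
head	9
tail	10
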