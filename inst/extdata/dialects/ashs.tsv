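name	code
CA1	1
CA2	2
DG	3
CA3	4
head	5
tail	6
subiculum	8
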