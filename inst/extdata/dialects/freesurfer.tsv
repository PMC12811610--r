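name	code
presubiculum	204
subiculum	205
CA1	206
CA3	208
CA4	209
DG	210
molecular_layer	214
tail	226
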