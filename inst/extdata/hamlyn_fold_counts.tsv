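fold	train_without_ps	train_with_ps	test_without_ps	test_with_ps
1	2036	3299	1639	920
2	1639	920	2036	3299
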