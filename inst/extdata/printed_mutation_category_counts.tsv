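type	category	count
synonymous	shared	42
synonymous	private_MW	40
synonymous	private_MD	3
replacement	shared	27
replacement	private_MW	23
replacement	private_MD	5
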