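cultivar	tuber_yield	starch_percent
Jutlandia	380	11.7
Desiree	478	15.4
Kuras	596	20.9
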