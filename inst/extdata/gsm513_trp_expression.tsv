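gene	log2_ratio
atoB	1.1150
yqeF	-1.8120
fadB	2.6340
sucA	1.8200
tnaA	1.4660
trpS	5.8490
katE	-0.4370
katG	1.4110
tynA	-0.7870
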