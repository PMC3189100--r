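trp_metabolism	synthetic miniature of tryptophan metabolism	atoB	yqeF	fadB	sucA	tnaA	trpS	katE	katG	tynA
fatty_acid_degradation	synthetic donor pathway	atoB	yqeF	fadB
butanoate_metabolism	synthetic donor pathway	atoB	yqeF
tca_cycle	synthetic donor pathway	sucA	fadB
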