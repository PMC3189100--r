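m_glycolysis	synthetic glycolysis-style module	hxk1	pfk1	pgi1	fba1	tpi1	eno1	pyk1
m_gluconeogenesis	synthetic gluconeogenesis-style module	fbp1	pck1	pgi1	fba1	tpi1	eno1
m_tca	synthetic TCA-style module	cit1	aco1	idh1	fba1
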