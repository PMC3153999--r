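gene	p_value
PIK3C3	1.97e-3
ATG12	8.16e-3
PRKAA2	8.28e-3
ATG5	1.45e-2
GABARAPL1	3.44e-2
BECN1	4.45e-2
IFNA13	4.72e-2
ATG7	4.92e-2
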