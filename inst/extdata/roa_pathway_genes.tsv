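gene	entrez_id	location
ATG12	9140	5q21-q22
ATG3	64422	3q13.2
ATG5	9474	6q21
ATG7	10533	3p25.3-p25.2
BECN1	8678	17q21
GABARAPL1	23710	12p13.2
IFNA1	3439	9p22
IFNA10	3446	9p22
IFNA13	3447	9p22
IFNA14	3448	9p22
IFNA16	3449	9p22
IFNA17	3451	9p22
IFNA2	3440	9p22
IFNA21	3452	9p22
IFNA4	3441	9P22
IFNA5	3442	9p22
IFNA6	3443	9p22
IFNA7	3444	9p22
IFNA8	3445	9p22
IFNG	3458	12q14
PIK3C3	5289	18q12.3
PIK3R4	30849	3q22.1
PRKAA1	5562	5p12
PRKAA2	5563	1p31
ULK2	9706	17p11.2
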