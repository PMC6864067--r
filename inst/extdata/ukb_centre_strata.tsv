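label	n_pairs	beta	ci_lo	ci_hi
Manchester	662	0.024	-0.088	0.0675
Oxford	669	-0.010	-0.088	0.067
Cardiff	930	0.022	-0.043	0.088
Glasgow	1046	0.072	0.019	0.125
Edinburgh	611	-0.047	-0.166	0.070
Stoke	1215	-0.012	-0.075	0.051
Reading	1352	0.003	-0.055	0.060
Bury	2244	0.012	-0.031	0.055
Newcastle	2976	-0.025	-0.064	0.013
Leeds	2563	0.041	0.001	0.081
Bristol	2117	0.015	-0.030	0.060
St Bartholomew's Hospital	122	-0.073	-0.220	0.074
Nottingham	2342	0.025	-0.017	0.066
Sheffield	2260	0.037	-0.009	0.082
Liverpool	2632	0.023	-0.020	0.066
Middlesbrough	1477	0.002	-0.050	0.053
Hounslow	838	0.073	-0.000	0.147
Croydon	1034	0.044	-0.027	0.115
Birmingham	1440	-0.019	-0.068	0.031
Swansea	85	-0.068	-0.283	0.146
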