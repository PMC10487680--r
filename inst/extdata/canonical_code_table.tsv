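res5	res35	wA	wC	wG	wU
N	D	0.0416666666666667	0.0416666666666667	0.0416666666666667	0.875
N	N	0.0416666666666667	0.875	0.0416666666666667	0.0416666666666667
S	D	0.0416666666666667	0.0416666666666667	0.875	0.0416666666666667
S	N	0.875	0.0416666666666667	0.0416666666666667	0.0416666666666667
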