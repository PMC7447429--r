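# Decay rates (1/s, mean +/- sd) of SSME transient currents triggered by
# a 200 mM ammonium or potassium pulse in proteoliposomes containing AmtB
# variants or NeRh50, at lipid-to-protein ratios (LPR) 10 and 5.
# NC = no transient current recorded.
variant	substrate	lpr	rate_mean	rate_sd
AmtB-WT	NH4	10	13.4	1.5
AmtB-WT	NH4	5	18.7	1.0
AmtB-WT	K	10	NC	NC
AmtB-WT	K	5	NC	NC
D160A	NH4	10	21.6	1.2
D160A	NH4	5	24.3	1.5
D160A	K	10	NC	NC
D160A	K	5	NC	NC
D160E	NH4	10	17.03	2.84
D160E	NH4	5	19.53	1.8
D160E	K	10	NC	NC
D160E	K	5	NC	NC
H168A-H318A	NH4	10	29.5	2.1
H168A-H318A	NH4	5	29.8	2.6
H168A-H318A	K	10	NC	NC
H168A-H318A	K	5	NC	NC
S219A-H168A-H318A	NH4	10	NC	NC
S219A-H168A-H318A	NH4	5	NC	NC
S219A-H168A-H318A	K	10	NC	NC
S219A-H168A-H318A	K	5	NC	NC
H168A	NH4	10	28.3	1.5
H168A	NH4	5	38.0	1.0
H168A	K	10	2.7	0.5
H168A	K	5	5.2	1.0
H318A	NH4	10	22.56	2.63
H318A	NH4	5	28.25	3.1
H318A	K	10	10.07	1.7
H318A	K	5	15.64	2.1
NeRh50	NH4	10	24.0	1.7
NeRh50	NH4	5	39.0	3.6
NeRh50	K	10	NC	NC
NeRh50	K	5	NC	NC
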