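# Brownian-dynamics association rate constants for the designed
# Z-domain/MyoD fusion models against target DNA (reference: wild-type
# MyoD bHLH/DNA complex). Columns: model label, k_on in 1/(M s), net charge.
label	k_on	net_charge
WT	4.66e8	5
Negative	0	-2
Seed	1.17e8	5
JW15	3.06e8	7
JW19	1.60e7	3
JW56	4.61e7	5
JW70	4.56e8	5
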