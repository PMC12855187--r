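# Multiplet library for the synthetic spectrum renderer.
# Approximate 500 MHz chemical shifts of serum metabolites, pH ~7.4;
# editable. rel_area is per unit concentration; width_ppm is the Lorentzian
# full width at half maximum. TSP and WATER rows are fixed features: the
# chemical-shift reference peak and the residual-water band.
metabolite	center_ppm	rel_area	width_ppm
2-aminobutyrate	0.98	3	0.012
2-aminobutyrate	1.89	2	0.016
2-aminobutyrate	3.71	1	0.012
alanine	1.48	3	0.010
alanine	3.78	1	0.012
anserine	2.67	2	0.016
anserine	3.21	3	0.016
anserine	7.10	1	0.014
anserine	8.20	1	0.014
glucose	3.24	1	0.014
glucose	3.41	2	0.014
glucose	3.54	2	0.014
glucose	3.73	2	0.014
glucose	3.84	1	0.014
glucose	4.64	0.4	0.012
glucose	5.23	0.6	0.010
glutamine	2.14	2	0.016
glutamine	2.45	2	0.016
glutamine	3.77	1	0.012
glycylproline	2.05	3	0.018
glycylproline	3.55	2	0.016
glycylproline	4.42	1	0.014
isoleucine	0.94	3	0.010
isoleucine	1.01	3	0.010
isoleucine	1.26	1	0.014
isoleucine	1.98	1	0.014
isoleucine	3.67	1	0.012
leucine	0.96	6	0.010
leucine	1.71	3	0.014
leucine	3.73	1	0.012
methionine	2.13	3	0.012
methionine	2.64	2	0.014
methionine	3.86	1	0.012
serine	3.84	1	0.012
serine	3.96	2	0.012
threonate	3.57	1	0.012
threonate	3.99	1	0.012
threonate	4.27	1	0.012
tryptophan	3.31	1	0.012
tryptophan	3.48	1	0.012
tryptophan	4.05	1	0.012
tryptophan	7.20	1	0.012
tryptophan	7.28	1	0.012
tryptophan	7.54	1	0.012
tryptophan	7.73	1	0.012
valine	0.99	3	0.010
valine	1.04	3	0.010
valine	2.28	1	0.014
valine	3.61	1	0.012
TSP	0.00	40	0.008
WATER	4.95	600	0.28
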