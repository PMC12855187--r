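# Synonym table consulted after lowercasing, stripping of D-/L- prefixes and
# removal of punctuation. Editable; one alias per row.
alias	canonical
glycilproline	glycylproline
glycylproline dipeptide	glycylproline
2aminobutyrate	2aminobutyrate
alphaaminobutyrate	2aminobutyrate
2aminobutyricacid	2aminobutyrate
alphaketoglutarate	2oxoglutarate
aketoglutarate	2oxoglutarate
glutamicacid	glutamate
asparticacid	aspartate
gaba	gammaaminobutyrate
bhydroxybutyrate	3hydroxybutyrate
betahydroxybutyrate	3hydroxybutyrate
vitaminc	ascorbate
ascorbicacid	ascorbate
threonicacid	threonate
lacticacid	lactate
pyruvicacid	pyruvate
gsh	glutathione
gssg	oxidizedglutathione
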