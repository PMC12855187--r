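Glucose-Alanine Cycle	Shuttle of amino groups from muscle to liver	alanine	glucose	pyruvate	glutamate	2-oxoglutarate	lactate
Alanine Metabolism	Transamination of alanine and pyruvate	alanine	pyruvate	glutamate	2-oxoglutarate
Glycine and Serine Metabolism	Interconversion of glycine, serine and one-carbon units	serine	glycine	threonine	cysteine	glutamate	methionine	choline	betaine	dimethylglycine	sarcosine	pyruvate
Glutathione Metabolism	Synthesis and turnover of the glutathione redox couple	glutathione	oxidized glutathione	cysteine	glycine	glutamate	glutamine	5-oxoproline	cysteinylglycine
Selenoamino Acid Metabolism	Metabolism of selenium-containing amino acids	selenomethionine	selenocysteine	selenohomocysteine	methionine	serine	cysteine
Tryptophan Metabolism	Kynurenine and serotonin branches of tryptophan catabolism	tryptophan	kynurenine	kynurenate	quinolinate	serotonin	melatonin	indoleacetate
Glutamate Metabolism	Glutamate/glutamine interconversion and amino-group transfer	glutamate	glutamine	2-oxoglutarate	gamma-aminobutyrate	glutathione	alanine
Valine Leucine and Isoleucine Degradation	Branched-chain amino acid catabolism	valine	leucine	isoleucine	3-methyl-2-oxovalerate	2-oxoisocaproate	2-oxoisovalerate	acetoacetate
Methionine Metabolism	Transmethylation and transsulfuration	methionine	homocysteine	cysteine	serine	betaine	dimethylglycine	2-aminobutyrate
Protein Biosynthesis	Incorporation of free amino acids into protein	alanine	arginine	asparagine	aspartate	cysteine	glutamine	glutamate	glycine	histidine	isoleucine	leucine	lysine	methionine	phenylalanine	proline	serine	threonine	tryptophan	tyrosine	valine
Urea Cycle	Disposal of nitrogen as urea	arginine	ornithine	citrulline	aspartate	urea	fumarate
Gluconeogenesis	De novo glucose synthesis from non-carbohydrate precursors	glucose	pyruvate	lactate	oxaloacetate	glycerol
Glycolysis	Oxidation of glucose to pyruvate	glucose	pyruvate	lactate
Ketone Body Metabolism	Synthesis and utilization of ketone bodies	acetoacetate	3-hydroxybutyrate	acetone
Ammonia Recycling	Reassimilation of free ammonia	glutamine	glutamate	glycine	serine	ammonia	asparagine
Histidine Metabolism	Histidine catabolism and imidazole dipeptides	histidine	anserine	carnosine	glutamate	urocanate
Ascorbate and Aldarate Metabolism	Vitamin C oxidation products	ascorbate	threonate	oxalate	dehydroascorbate
Collagen Degradation	Proline-containing dipeptides from collagen turnover	glycylproline	proline	glycine	hydroxyproline
Phenylalanine and Tyrosine Metabolism	Aromatic amino acid catabolism	phenylalanine	tyrosine	4-hydroxyphenylpyruvate
Purine Metabolism	Purine nucleotide turnover	hypoxanthine	xanthine	urate	inosine	adenosine
Taurine and Hypotaurine Metabolism	Sulfonic acid derivatives of cysteine	taurine	hypotaurine	cysteine
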