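name	formula	pathway	amine	polarity
glycine	C2H5NO2	amino acid metabolism	TRUE	pos
GABA	C4H9NO2	neurotransmitter	TRUE	pos
glutamate	C5H9NO4	glutaminolysis	TRUE	both
glutamine	C5H10N2O3	glutaminolysis	TRUE	both
aspartate	C4H7NO4	amino acid metabolism	TRUE	both
serine	C3H7NO3	amino acid metabolism	TRUE	pos
N-acetylaspartate	C6H9NO5	neuronal metabolism	FALSE	neg
lactate	C3H6O3	glycolysis	FALSE	neg
pyruvate	C3H4O3	glycolysis	FALSE	neg
succinate	C4H6O4	TCA cycle	FALSE	neg
fumarate	C4H4O4	TCA cycle	FALSE	neg
malate	C4H6O5	TCA cycle	FALSE	neg
citrate	C6H8O7	TCA cycle	FALSE	neg
isocitrate	C6H8O7	TCA cycle	FALSE	neg
alpha-ketoglutarate	C5H6O5	TCA cycle	FALSE	neg
glucose	C6H12O6	glycolysis	FALSE	neg
glucose 6-phosphate	C6H13O9P	glycolysis	FALSE	neg
fructose 6-phosphate	C6H13O9P	glycolysis	FALSE	neg
3-phosphoglycerate	C3H7O7P	glycolysis	FALSE	neg
ribose 5-phosphate	C5H11O8P	pentose phosphate pathway	FALSE	neg
gluconate 6-phosphate	C6H13O10P	pentose phosphate pathway	FALSE	neg
AMP	C10H14N5O7P	nucleotide metabolism	FALSE	neg
ADP	C10H15N5O10P2	nucleotide metabolism	FALSE	neg
ATP	C10H16N5O13P3	nucleotide metabolism	FALSE	neg
UDP-glucose	C15H24N2O17P2	hexosamine pathway	FALSE	neg
UDP-N-acetylglucosamine	C17H27N3O17P2	hexosamine pathway	FALSE	neg
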