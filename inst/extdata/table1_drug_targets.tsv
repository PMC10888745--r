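drug_id	drug_name	target_gene_symbol	target_uniprot_id	action	target_protein_name
DB00987	Cytarabine	POLB	P06746	inhibitor	DNA polymerase beta
DB00877	Sirolimus	MTOR	P42345	inhibitor	Serine/threonine-protein kinase mTOR
DB01073	Fludarabine	POLA1	P09884	inhibitor	DNA polymerase alpha catalytic subunit
DB01073	Fludarabine	RRM1	P23921	inhibitor	Ribonucleoside-diphosphate reductase large subunit
DB00091	Cyclosporine	PPP3R2	Q96LZ3	inhibitor	Calcineurin subunit B type 2
DB00091	Cyclosporine	PPIA	P62937	inhibitor	Peptidyl-prolyl cis-trans isomerase A
DB00392	Profenamine	CHRM1	P11229	antagonist	Muscarinic acetylcholine receptor M1
DB00392	Profenamine	CHRM2	P08172	antagonist	Muscarinic acetylcholine receptor M2
DB00392	Profenamine	GRIN3A	Q8TCU5	antagonist	Glutamate receptor ionotropic, NMDA 3A
DB00831	Trifluoperazine	DRD2	P14416	antagonist	Dopamine D2 receptor
DB00831	Trifluoperazine	CALY	Q9NYX4	inhibitor	Neuron-specific vesicular protein calcyon
DB00831	Trifluoperazine	ADRA1A	P35348	antagonist	Alpha-1A adrenergic receptor
DB00831	Trifluoperazine	CALM	P0DP23	inhibitor	Calmodulin
DB00831	Trifluoperazine	S100A4	P26447	inhibitor	Protein S100-A4
DB00694	Daunorubicin	TOP2A	P11388	inhibitor	DNA topoisomerase 2-alpha
DB00694	Daunorubicin	TOP2B	Q02880	inhibitor	DNA topoisomerase 2-beta
DB00390	Digoxin	ATP1A1	P05023	inhibitor	Sodium/potassium-transporting ATPase subunit alpha-1
DB01030	Topotecan	TOP1	P11387	inhibitor	DNA topoisomerase 1
DB01030	Topotecan	TOP1MT	Q969P6	inhibitor	DNA topoisomerase I, mitochondrial
DB00997	Doxorubicin	TOP1	P11387	inhibitor	DNA topoisomerase 1
DB00997	Doxorubicin	TOP2A	P11388	inhibitor	DNA topoisomerase 2-alpha
DB00997	Doxorubicin	TOP2B	Q02880	inhibitor	DNA topoisomerase 2-beta
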