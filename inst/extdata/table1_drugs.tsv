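rank	perturbagen_id	drug_id	drug_name	mean_zhang_score
1	BRD-K33106058_DB00987	DB00987	Cytarabine	0.402339
2	BRD-K89626439_DB00877	DB00877	Sirolimus	0.396491
3	BRD-K72238567_DB01073	DB01073	Fludarabine	0.20117
4	BRD-A38030642_DB00091	DB00091	Cyclosporine	0.192982
5	BRD-A16311756_DB00392	DB00392	Profenamine	0.166082
6	BRD-K89732114_DB00831	DB00831	Trifluoperazine	0.153216
7	BRD-K43389675_DB00694	DB00694	Daunorubicin	0.145029
8	BRD-K23478508_DB00390	DB00390	Digoxin	0.138012
9	BRD-A59985574_DB01030	DB01030	Topotecan	0.127485
10	BRD-K04548931_DB00997	DB00997	Doxorubicin	0.100585
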