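component	type	unit	standard_zero	standard_max	max_points
total_fruits	adequacy	per_1000kcal	0	0.8	5
whole_fruits	adequacy	per_1000kcal	0	0.4	5
total_vegetables	adequacy	per_1000kcal	0	1.1	5
greens_and_beans	adequacy	per_1000kcal	0	0.2	5
whole_grains	adequacy	per_1000kcal	0	1.5	10
dairy	adequacy	per_1000kcal	0	1.3	10
total_protein_foods	adequacy	per_1000kcal	0	2.5	5
seafood_plant_proteins	adequacy	per_1000kcal	0	0.8	5
fatty_acids	adequacy	per_1000kcal	1.2	2.5	10
refined_grains	moderation	per_1000kcal	4.3	1.8	10
sodium	moderation	per_1000kcal	2.0	1.1	10
added_sugars	moderation	percent_energy	26	6.5	10
saturated_fats	moderation	percent_energy	16	8	10
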