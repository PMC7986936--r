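region	state	state_name	hemisphere	lobe
precentral_L	1	precentral	L	frontal
precentral_R	1	precentral	R	frontal
superior_frontal_L	2	superior_frontal	L	frontal
superior_frontal_R	2	superior_frontal	R	frontal
middle_frontal_L	3	middle_frontal	L	frontal
middle_frontal_R	3	middle_frontal	R	frontal
inferior_frontal_L	4	inferior_frontal	L	frontal
inferior_frontal_R	4	inferior_frontal	R	frontal
orbital_gyrus_L	5	orbital_gyrus	L	frontal
orbital_gyrus_R	5	orbital_gyrus	R	frontal
supplementary_motor_L	6	supplementary_motor	L	frontal
supplementary_motor_R	6	supplementary_motor	R	frontal
cingulate_L	7	cingulate	L	limbic
cingulate_R	7	cingulate	R	limbic
parahippocampal_L	8	parahippocampal	L	limbic
parahippocampal_R	8	parahippocampal	R	limbic
entorhinal_L	9	entorhinal	L	limbic
entorhinal_R	9	entorhinal	R	limbic
superior_temporal_L	10	superior_temporal	L	temporal
superior_temporal_R	10	superior_temporal	R	temporal
middle_temporal_L	11	middle_temporal	L	temporal
middle_temporal_R	11	middle_temporal	R	temporal
inferior_temporal_L	12	inferior_temporal	L	temporal
inferior_temporal_R	12	inferior_temporal	R	temporal
temporal_pole_L	13	temporal_pole	L	temporal
temporal_pole_R	13	temporal_pole	R	temporal
planum_temporale_L	14	planum_temporale	L	temporal
planum_temporale_R	14	planum_temporale	R	temporal
fusiform_L	15	fusiform	L	temporal
fusiform_R	15	fusiform	R	temporal
postcentral_L	16	postcentral	L	parietal
postcentral_R	16	postcentral	R	parietal
superior_parietal_L	17	superior_parietal	L	parietal
superior_parietal_R	17	superior_parietal	R	parietal
supramarginal_L	18	supramarginal	L	parietal
supramarginal_R	18	supramarginal	R	parietal
angular_L	19	angular	L	parietal
angular_R	19	angular	R	parietal
precuneus_L	20	precuneus	L	parietal
precuneus_R	20	precuneus	R	parietal
calcarine_L	21	calcarine	L	occipital
calcarine_R	21	calcarine	R	occipital
cuneus_L	22	cuneus	L	occipital
cuneus_R	22	cuneus	R	occipital
lingual_L	23	lingual	L	occipital
lingual_R	23	lingual	R	occipital
middle_occipital_L	24	middle_occipital	L	occipital
middle_occipital_R	24	middle_occipital	R	occipital
occipital_pole_L	25	occipital_pole	L	occipital
occipital_pole_R	25	occipital_pole	R	occipital
caudate_L	26	caudate	L	subcortical
caudate_R	26	caudate	R	subcortical
putamen_L	27	putamen	L	subcortical
putamen_R	27	putamen	R	subcortical
white_matter	28	white_matter	bilateral	white_matter
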