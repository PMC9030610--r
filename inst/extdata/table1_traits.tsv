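herb_id	display_name	properties	meridians	actions
A_dahurica	A. dahurica	Pungent and warm.	Lung, stomach and large intestine.	expel wind and release exterior; alleviate pain; relieve stuffy nose; dry dampness; stop leucorrhoea
A_pubescens	A. pubescens	Pungent, bitter, slightly warm.	Liver, kidney, and lung.	dispel wind-damp; alleviate pain; release exterior
A_sinensis	A. sinensis	Sweet, pungent, warm.	Heart and liver.	tonify blood; activate blood; alleviate pain; regulate menstruation; moisten intestines
A_membranaceus	A. membranaceus	Sweet, warm.	Lung and spleen.	tonify qi; raise yang; tonify defensive aspect to secure superficial; relieve edema through diuretic; dispel toxin to promote skin generation; nourish blood
A_macrocephala	A. macrocephala	Sweet, bitter, warm.	Spleen and stomach.	tonify spleen qi; dry dampness; induce diuresis; arrest sweating; prevent abortion
C_pilosula	C. pilosula	Sweet, neutral.	Lung and spleen.	invigorate lung-qi and spleen-qi; nourish blood; promote the generation of body fluid
C_chinensis	C. chinensis	Bitter, cold.	Heart, stomach, large intestine and liver.	clear heat and dry dampness; purge fire and relieve toxicity
C_aromatica	C. aromatica	Pungent, bitter, cold.	Liver, gallbladder and heart.	activate blood and alleviate pain; move qi and relieve depression; clear heat and cool blood; promote excretion of bile and remove jaundice
F_suspensa	F. suspensa	Bitter, slightly pungent, cold.	Lung, heart and small intestine.	clear heat and remove toxicity; disperse wind-heat; clear heart-heat
L_edodes	L. edodes	Sweet, neutral.	Liver and stomach.	tonify deficiency; strengthen the spleen; stimulate the appetite; expel wind; promote eruption; resolve phlegm and regulate the flow of qi; remove toxicity and treat cancer
P_lactiflora	P. lactiflora	Bitter, sour, sweet, slightly cold.	Spleen and liver.	tonify blood; astringe yin to check sweating; emolliate liver to alleviate pain; calm and suppress liver yang
P_amurense	P. amurense	Bitter, cold.	Liver, gallbladder, large intestine, kidney and bladder.	clear heat and dry dampness; purge fire and remove toxicity; subdue deficiency heat
P_cocos	P. cocos	Sweet, bland, neutral.	Heart, spleen, and kidney.	induce diuresis and drain dampness; invigorate spleen; induce tranquilization
R_glutinosa	R. glutinosa	Sweet, bitter, cold.	Heart, liver, stomach and kidney.	clear heat and cool blood; stop bleeding; nourish yin
S_baicalensis	S. baicalensis	Bitter, cold.	Lung, stomach, gallbladder, large intestine or bladder.	clear heat and dry dampness; purge fire and relieve toxicity; cool blood; stop bleeding
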