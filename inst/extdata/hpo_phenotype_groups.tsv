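hpo_id	group	label
HP:0009713	CHB	Spinal hemangioblastoma
HP:0006880	CHB	Cerebellar hemangioblastoma
HP:0010797	CHB	Hemangioblastoma
HP:0009594	RA	Retinal capillary hemangioma
HP:0002666	PPGL	Pheochromocytoma
HP:0002668	PPGL	Paraganglioma
HP:0005584	RCC	Renal cell carcinoma
HP:0012197	PNET	Pancreatic endocrine tumor
HP:0031520	ELST	Endolymphatic sac tumor
HP:0001737	PCT	Pancreatic cysts
HP:0002894	PCT	Neoplasm of the pancreas
HP:0000107	RCT	Renal cyst
HP:0100964	ECT	Epididymal cyst
HP:0000138	OCT	Ovarian cyst
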