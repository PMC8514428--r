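morphology_code	site_code	category_id	subclass
8140/3	C18	colorectal_ac	adenocarcinoma
8140/3	C34	lung_ac	adenocarcinoma
8070/3	C34	lung_scc	squamous_cell_carcinoma
8720/3	*	melanoma	malignant_melanoma
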