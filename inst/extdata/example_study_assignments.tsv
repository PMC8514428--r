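study_id	selector_type	selector_value	category_id
lung_study	metadata	histology=squamous	lung_scc
lung_study	default		lung_ac
skin_study	default		melanoma
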