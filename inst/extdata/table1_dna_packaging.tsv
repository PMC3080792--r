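# Proteins annotated to DNA packaging that were identified in the membrane
# fraction, with curated subcellular specificity. Transcribed from the
# published table.
protein_id	accession	description	locations
JS40011197	O88807	Protein-arginine deiminase type-4	Cytoplasm
JS40071128	O88764	Death-associated protein kinase 3	Nuclear; relocates to the cytoplasm
JS40026124	Q923V8	15 kDa selenoprotein precursor	Endoplasmic reticulum lumen
JS40021817	Q63945	Protein SET	Cytoplasm, Endoplasmic reticulum, Nucleus
JS40021552	Q9Z2G8	Nucleosome assembly protein 1-like 1	Nucleus, Melanosome
JS40048134	NP_445899.1	Histone deacetylase 2	Nucleus
JS40016703	Q6AYU1	Mortality factor 4-like protein 1	Nucleus
JS40021952	Q6P747	Heterochromatin protein 1, binding protein 3	Nucleus
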