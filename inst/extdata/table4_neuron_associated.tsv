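# Proteins regarded as primarily neuron-associated that were identified in
# the membrane fraction, with abundance (ng per mg membrane protein), P/H
# ratio ("inf" = detected in P only), curated location and reported tissue
# specificity. Transcribed from the published table; the Reticulon 3 P/H of
# 416.78 is preserved as printed even though the surrounding narrative
# states a 0.5-5 range for this group.
protein_id	accession	description	abundance_P_ng_per_mg	ratio_PH	locations	tissue_specificity
JS40001915	Q9Z270	Vesicle-associated membrane protein-associated protein A	645.54	0.523	Plasma membrane; vesicle	Ubiquitous
JS40008100	NP_001100068	catenin (cadherin associated protein), alpha 2 (N-catenin)	461.25	3.92	plasma membrane, Cytoskeleton, cell junction	Brain
JS40003261	Q9JK11	Reticulon-4 (nogo)	343.33	1.09	Endoplasmic reticulum	mainly nervous system
JS40015951	Q9Z269	Vesicle-associated membrane protein-associated protein B	267.42	0.461	Plasma membrane; vesicle	Ubiquitous
JS40003589	Q9QWJ9	Neuropilin-1, CD304	218.03	2.342	Plasma membrane	Neuron and EC
JS40013915	Q9JLU4	Shank3 (Proline-rich synapse associated protein 2)	172.77	4.844	Plasma membrane; cytoplasm, synapse	Widely expressed in brain
JS40001396	Q64548	Reticulon-1	85.81	3.637	Endoplasmic reticulum	central and peripheral nervous system
JS40046849	Q6GMN2	Brain-specific angiogenesis inhibitor 1-associated protein 2	25.66	inf	Plasma membrane; cytoplasm, cell projection	Ubiquitous
JS40014656	O08816	Neural Wiskott-Aldrich syndrome protein	16.95	inf	Cytoskeleton; nucleus	NA
JS40028986	NP_001101576	Plexin-B2	14.73	0.553	Plasma membrane	NA
JS40004987	Q63198	Contactin-1 (Neural cell surface protein F3)	7.97	inf	Plasma membrane	NA
JS40001709	Q6RJR6	Reticulon 3 protein	2	416.78	golgi; ER	many tissues
JS40039470	Q8NFP9	Neurobeachin	1.85	inf	Peripheral membrane, cytoplasm	Predominant in many brain structures
JS40011947	P21263	Nestin	1.17	inf	unknown	CNS stem cell
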