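dataset	context	drug_name	actual_effect	predicted_effect	rank_obs	n_cand
GSE62504	HCC827-BR1	Afatinib	resistant	resistant	7	130
GSE62504	HCC827-BR1	Dasatinib	sensitive	sensitive	2	130
GSE62504	HCC827-BR2	Afatinib	resistant	resistant	6	118
GSE62504	HCC827-BR2	Dasatinib	sensitive	resistant	NA	NA
GSE129221	PC9	Gefitinib	resistant	resistant	30	149
GSE129221	PC9	Apatinib	sensitive	not_observed	NA	NA
GSE200029	T47D	Tamoxifen	resistant	resistant	6	172
GSE200029	T47D	Erdatinib	sensitive	sensitive	13	172
GSE268699	MCF7	Palbociclib	resistant	resistant	52	84
GSE268699	MCF7	Fulvestrant	resistant	resistant	3	188
GSE268699	T47D	Palbociclib	resistant	sensitive	NA	NA
GSE268699	T47D	Fulvestrant	resistant	not_observed	NA	NA
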