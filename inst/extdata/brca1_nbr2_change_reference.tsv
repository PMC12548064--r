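# Published within-child change results for the 25 BRCA1/NBR2 promoter CpGs
# from a two-timepoint ART birth-cohort study: regression of the
# within-child difference in DNAm between birth and later age on ART and
# maternal covariates.
# Coefficients in standardized-residual-difference units; 3-decimal rounding
# as printed. p_fdr is the published Benjamini-Hochberg value.
probe_id	beta_hat	ci_low	ci_high	p_raw	p_fdr
cg08386886	-0.067	-0.184	0.049	0.258	0.785
cg24806953	-0.016	-0.085	0.054	0.661	0.787
cg20187250	-0.038	-0.108	0.032	0.287	0.785
cg15419295	-0.020	-0.094	0.053	0.587	0.787
cg16963062	-0.019	-0.092	0.054	0.609	0.787
cg16630982	0.088	0.012	0.165	0.025	0.488
cg21253966	-0.023	-0.096	0.051	0.547	0.787
cg04110421	-0.056	-0.187	0.076	0.408	0.787
cg04658354	0.065	-0.064	0.194	0.326	0.785
cg17301289	0.002	-0.136	0.140	0.976	0.976
cg09441966	-0.045	-0.188	0.099	0.544	0.787
cg26891576	-0.031	-0.171	0.108	0.660	0.787
cg10893007	-0.079	-0.207	0.049	0.229	0.785
cg12182452	-0.088	-0.213	0.037	0.170	0.785
cg09831010	0.073	-0.063	0.209	0.294	0.785
cg25067162	-0.020	-0.105	0.064	0.636	0.787
cg26276233	-0.119	-0.231	-0.006	0.039	0.488
cg06001716	-0.114	-0.241	0.013	0.080	0.664
cg02286533	-0.034	-0.114	0.047	0.415	0.787
cg14947218	0.009	-0.060	0.079	0.795	0.903
cg16006004	-0.007	-0.113	0.099	0.899	0.976
cg18372208	-0.052	-0.161	0.056	0.345	0.785
cg14687474	0.003	-0.092	0.098	0.950	0.976
cg25288140	0.043	-0.138	0.223	0.643	0.787
cg27581762	0.100	-0.041	0.241	0.165	0.785
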