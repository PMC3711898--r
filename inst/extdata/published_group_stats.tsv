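# Printed reference values of the grouped statistical analysis over the
# 37-strain analysis set (NA where the source prints no value).
test	parameter_x	parameter_y	p_value	df	r_squared	f_value	correlation	significant
pearson_regression	glc_cons_rate	biomass_yield	1.42E-06	35	0.49	33.64	-0.70	TRUE
pearson_regression	glc_cons_rate	growth_rate	1.98E-02	35	0.15	5.96	0.38	TRUE
pearson_regression	ethanol_yield	growth_rate	5.72E-01	35	0.01	0.33	0.38	FALSE
spearman	glc_cons_rate	biomass_yield	2.60E-06	NA	NA	NA	-0.69	TRUE
spearman	glc_cons_rate	growth_rate	3.63E-02	NA	NA	NA	0.35	TRUE
spearman	ethanol_yield	growth_rate	3.63E-02	NA	NA	NA	-0.10	TRUE
anova	groups	biomass_yield	1.44E-14	33	0.87	72.01	NA	TRUE
anova	groups	ethanol_yield	4.90E-13	33	0.84	55.94	NA	TRUE
anova	groups	glc_cons_rate	2.00E-05	33	0.52	11.88	NA	TRUE
anova	groups	growth_rate	7.60E-01	33	0.03	0.40	NA	FALSE
kruskal_wallis	groups	biomass_yield	7.14E-06	3	NA	NA	NA	TRUE
kruskal_wallis	groups	ethanol_yield	6.62E-06	3	NA	NA	NA	TRUE
kruskal_wallis	groups	glc_cons_rate	2.13E-04	3	NA	NA	NA	TRUE
kruskal_wallis	groups	growth_rate	6.00E-01	3	NA	NA	NA	FALSE
welch_t	biomass_yield	group 1 vs group 2	5.26E-07	11.82	NA	NA	NA	TRUE
welch_t	biomass_yield	group 1 vs group 3	4.80E-06	9.18	NA	NA	NA	TRUE
welch_t	biomass_yield	group 1 vs group 4	7.68E-09	14.93	NA	NA	NA	TRUE
welch_t	biomass_yield	group 2 vs group 3	5.95E-02	4.07	NA	NA	NA	FALSE
welch_t	biomass_yield	group 2 vs group 4	7.39E-04	21.00	NA	NA	NA	TRUE
welch_t	biomass_yield	group 3 vs group 4	9.76E-01	5.30	NA	NA	NA	FALSE
welch_t	ethanol_yield	group 1 vs group 2	1.46E-06	13.79	NA	NA	NA	TRUE
welch_t	ethanol_yield	group 1 vs group 3	4.37E-04	4.79	NA	NA	NA	TRUE
welch_t	ethanol_yield	group 1 vs group 4	3.81E-12	22.69	NA	NA	NA	TRUE
welch_t	ethanol_yield	group 2 vs group 3	7.18E-02	6.04	NA	NA	NA	FALSE
welch_t	ethanol_yield	group 2 vs group 4	1.77E-03	16.28	NA	NA	NA	TRUE
welch_t	ethanol_yield	group 3 vs group 4	5.45E-01	5.29	NA	NA	NA	FALSE
welch_t	glc_cons_rate	group 1 vs group 2	2.03E-06	15.84	NA	NA	NA	TRUE
welch_t	glc_cons_rate	group 1 vs group 3	2.49E-02	3.53	NA	NA	NA	TRUE
welch_t	glc_cons_rate	group 1 vs group 4	7.67E-06	17.68	NA	NA	NA	TRUE
welch_t	glc_cons_rate	group 2 vs group 3	4.24E-01	3.50	NA	NA	NA	FALSE
welch_t	glc_cons_rate	group 2 vs group 4	1.59E-02	17.39	NA	NA	NA	TRUE
welch_t	glc_cons_rate	group 3 vs group 4	3.45E-01	7.19	NA	NA	NA	FALSE
welch_t	growth_rate	group 1 vs group 2	9.97E-01	12.78	NA	NA	NA	FALSE
welch_t	growth_rate	group 1 vs group 3	4.46E-01	7.33	NA	NA	NA	FALSE
welch_t	growth_rate	group 1 vs group 4	5.31E-01	17.02	NA	NA	NA	FALSE
welch_t	growth_rate	group 2 vs group 3	3.89E-01	3.98	NA	NA	NA	FALSE
welch_t	growth_rate	group 2 vs group 4	3.67E-01	21.00	NA	NA	NA	FALSE
welch_t	growth_rate	group 3 vs group 4	7.39E-01	5.10	NA	NA	NA	FALSE
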