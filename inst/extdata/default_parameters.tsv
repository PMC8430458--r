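name	value	low	high	distribution	units	source
surgical_mortality	0.0017	0.0014	0.0020	beta	probability	hysterectomy outcomes series
complication_prob	0.030	0.010	0.044	beta	probability	benign hysterectomy trials
oc_screen_sens	0.600	0.540	0.660	beta	probability	TVUS plus CA-125 screening
oc_screen_spec	0.962	0.866	0.980	beta	probability	TVUS plus CA-125 screening
ec_screen_sens	0.910	0.819	0.980	beta	probability	pelvic exam with endometrial biopsy
ec_screen_spec	0.980	0.960	0.980	beta	probability	pelvic exam with endometrial biopsy
rr_salpingectomy_oc	1.00	0.75	1.00	beta	risk ratio	salpingectomy observational studies
rr_oophorectomy_mortality	1.00	1.00	1.40	none	risk ratio	early-menopause mortality literature
ec_cum_risk_MLH1	0.370	0.301	0.465	normal	fraction	prospective carrier registry
ec_cum_risk_MSH2	0.489	0.402	0.607	normal	fraction	prospective carrier registry
ec_cum_risk_MSH6	0.411	0.286	0.615	normal	fraction	prospective carrier registry
ec_cum_risk_PMS2	0.118	0.036	0.200	normal	fraction	PMS2 cohort study
oc_cum_risk_MLH1	0.110	0.074	0.197	normal	fraction	prospective carrier registry
oc_cum_risk_MSH2	0.174	0.118	0.312	normal	fraction	prospective carrier registry
oc_cum_risk_MSH6	0.108	0.037	0.339	normal	fraction	prospective carrier registry
oc_cum_risk_PMS2	0.030	0.006	0.474	normal	fraction	PMS2 cohort study
ec_stage_noint_local	0.73	0.58	0.86	normal	fraction	SEER stage distribution
ec_stage_noint_regional	0.19	0.12	0.36	normal	fraction	SEER stage distribution
ec_stage_noint_distant	0.08	0.02	0.08	normal	fraction	SEER stage distribution
ec_stage_surv_local	0.86	0.72	0.98	normal	fraction	surveillance program series
ec_stage_surv_regional	0.13	0.02	0.25	normal	fraction	surveillance program series
ec_stage_surv_distant	0.01	0.002	0.03	normal	fraction	surveillance program series
ec_surv5_local	0.950	0.760	0.980	beta	fraction	SEER relative survival
ec_surv5_regional	0.699	0.552	0.980	beta	fraction	SEER relative survival
ec_surv5_distant	0.168	0.134	0.202	beta	fraction	SEER relative survival
oc_stage_noint_local	0.16	0.08	0.20	normal	fraction	SEER stage distribution
oc_stage_noint_regional	0.23	0.18	0.32	normal	fraction	SEER stage distribution
oc_stage_noint_distant	0.61	0.48	0.74	normal	fraction	SEER stage distribution
oc_stage_surv_local	0.67	0.50	0.98	normal	fraction	surveillance program series
oc_stage_surv_regional	0.17	0.02	0.42	normal	fraction	surveillance program series
oc_stage_surv_distant	0.16	0.00	0.08	normal	fraction	surveillance program series
oc_stage_rrs_local	0.80	0.60	0.85	normal	fraction	risk-reducing surgery series
oc_stage_rrs_regional	0.05	0.04	0.16	normal	fraction	risk-reducing surgery series
oc_stage_rrs_distant	0.15	0.11	0.24	normal	fraction	risk-reducing surgery series
oc_surv5_local	0.924	0.739	0.980	beta	fraction	SEER relative survival
oc_surv5_regional	0.752	0.602	0.902	beta	fraction	SEER relative survival
oc_surv5_distant	0.292	0.234	0.350	beta	fraction	SEER relative survival
util_healthy_start	1.00	NA	NA	none	utility	population norms, age adjusted
util_healthy_end	0.82	NA	NA	none	utility	population norms, age adjusted
util_hystbso_premenopausal	0.90	0.77	0.95	normal	utility	surgical menopause utility studies
util_hystbso_postmenopausal	1.00	0.95	1.00	normal	utility	benign hysterectomy trials
util_hystbs	1.00	0.95	1.00	normal	utility	benign hysterectomy trials
util_ec_local	0.83	0.73	0.93	normal	utility	gynecologic cancer utility study
util_ec_regional	0.83	0.73	0.93	normal	utility	gynecologic cancer utility study
util_ec_distant	0.59	0.49	0.69	normal	utility	gynecologic cancer utility study
util_oc_local	0.75	0.65	0.85	normal	utility	gynecologic cancer utility study
util_oc_regional	0.75	0.65	0.85	normal	utility	gynecologic cancer utility study
util_oc_distant	0.59	0.49	0.69	normal	utility	gynecologic cancer utility study
disutil_surgery	-0.025	-0.035	-0.015	normal	utility decrement	benign hysterectomy trials
disutil_surgery_complication	-0.0425	-0.0545	-0.0325	normal	utility decrement	benign hysterectomy trials
disutil_screen	-0.0008	-0.0010	-0.0003	normal	utility decrement	assumed, one third of a day
cost_surveillance_initial	1920	1536	2304	gamma	2020 USD	screening cost analysis
cost_surveillance_subsequent	1376	1101	1651	gamma	2020 USD	screening cost analysis
cost_hysterectomy	8922	6941	11586	gamma	2020 USD	surgical cost analysis
cost_oophorectomy	6155	4657	8508	gamma	2020 USD	surgical cost analysis
cost_complication	8276	6621	9931	gamma	2020 USD	surgical cost analysis
cost_ec_initial_local	22821	21707	23937	gamma	2020 USD	phase-of-care cost study
cost_ec_initial_regional	42396	38837	45955	gamma	2020 USD	phase-of-care cost study
cost_ec_initial_distant	71074	61147	81001	gamma	2020 USD	phase-of-care cost study
cost_ec_continuing	1532	1355	1711	gamma	2020 USD	phase-of-care cost study
cost_ec_terminal	41226	39751	42699	gamma	2020 USD	phase-of-care cost study
cost_oc_initial_local	50653	43801	57504	gamma	2020 USD	phase-of-care cost study
cost_oc_initial_regional	70056	58998	81112	gamma	2020 USD	phase-of-care cost study
cost_oc_initial_distant	97312	92875	101750	gamma	2020 USD	phase-of-care cost study
cost_oc_continuing	6509	5914	7104	gamma	2020 USD	phase-of-care cost study
cost_oc_terminal	83876	80951	86799	gamma	2020 USD	phase-of-care cost study
discount_rate	0.03	NA	NA	none	annual rate	US panel convention
wtp	100000	NA	NA	none	USD per QALY	US willingness-to-pay convention
start_age	25	NA	NA	none	years	model design
end_age	75	NA	NA	none	years	model design
min_intervention_age	30	NA	NA	none	years	guideline earliest intervention
menopause_age	50	NA	NA	none	years	mean natural menopause
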