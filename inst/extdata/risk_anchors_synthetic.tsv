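# Synthetic reconstruction of the age shape of gene-specific cumulative
# cancer incidence (the age-specific penetrance curves themselves are not
# reproduced here; interior anchors were back-derived from published
# cumulative incidences at the risk-reducing-surgery ages, final anchors are
# the published age-75 cumulative risks).  Piecewise-constant conditional
# annual probabilities are assumed between anchors; onset is zero before 30.
gene	site	age	cum_inc
MLH1	EC	30	0
MLH1	EC	35	0.0095
MLH1	EC	40	0.0187
MLH1	EC	75	0.370
MLH1	OC	30	0
MLH1	OC	35	0.0100
MLH1	OC	40	0.0197
MLH1	OC	50	0.0589
MLH1	OC	75	0.110
MSH2	EC	30	0
MSH2	EC	35	0.0115
MSH2	EC	40	0.0226
MSH2	EC	75	0.489
MSH2	OC	30	0
MSH2	OC	35	0.0110
MSH2	OC	40	0.0216
MSH2	OC	75	0.174
MSH6	EC	30	0
MSH6	EC	35	0.0115
MSH6	EC	40	0.0226
MSH6	EC	75	0.411
MSH6	OC	30	0
MSH6	OC	35	0.0115
MSH6	OC	40	0.0226
MSH6	OC	50	0.0498
MSH6	OC	75	0.108
PMS2	EC	30	0
PMS2	EC	40	0.0019
PMS2	EC	50	0.0068
PMS2	EC	75	0.118
PMS2	OC	30	0
PMS2	OC	50	0
PMS2	OC	75	0.030
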