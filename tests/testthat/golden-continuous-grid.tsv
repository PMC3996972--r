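policy	odds_ratio	par_percent	sensitivity	specificity	rpb_ea	rpb_breast	rpb_ovarian	nb_ea	nb_breast	nb_ovarian
fixed_sensitivity	1.5	33.22	0.95	0.07	-0.456	-0.659	-0.812	-0.018	-0.046	-0.129
fixed_sensitivity	2	48.88	0.95	0.09	-0.440	-0.641	-0.792	-0.017	-0.045	-0.126
fixed_sensitivity	4	71.30	0.95	0.16	-0.389	-0.583	-0.728	-0.015	-0.040	-0.115
fixed_sensitivity	10	84.46	0.95	0.29	-0.287	-0.466	-0.601	-0.011	-0.032	-0.095
fixed_sensitivity	20	89.01	0.95	0.43	-0.187	-0.352	-0.475	-0.007	-0.024	-0.075
fixed_sensitivity	50	92.25	0.95	0.61	-0.051	-0.196	-0.305	-0.002	-0.014	-0.048
fixed_specificity	1.5	2.59	0.08	0.95	-0.019	-0.032	-0.043	-0.001	-0.002	-0.007
fixed_specificity	2	4.95	0.10	0.95	-0.013	-0.029	-0.041	-0.001	-0.002	-0.007
fixed_specificity	4	12.67	0.17	0.95	0.006	-0.018	-0.036	0.000	-0.001	-0.006
fixed_specificity	10	27.40	0.31	0.95	0.041	0.002	-0.028	0.002	0.000	-0.004
fixed_specificity	20	41.15	0.44	0.95	0.074	0.021	-0.019	0.003	0.001	-0.003
fixed_specificity	50	60.16	0.62	0.95	0.119	0.047	-0.008	0.005	0.003	-0.001
balanced	1.5	14.83	0.54	0.54	-0.208	-0.316	-0.397	-0.008	-0.022	-0.063
balanced	2	23.89	0.57	0.57	-0.178	-0.285	-0.366	-0.007	-0.020	-0.058
balanced	4	42.57	0.64	0.63	-0.114	-0.222	-0.304	-0.005	-0.015	-0.048
balanced	10	60.28	0.72	0.72	-0.030	-0.137	-0.218	-0.001	-0.010	-0.035
balanced	20	70.68	0.78	0.77	0.024	-0.085	-0.166	0.001	-0.006	-0.026
balanced	50	80.17	0.84	0.84	0.088	-0.020	-0.101	0.003	-0.001	-0.016
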