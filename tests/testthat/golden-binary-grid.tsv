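odds_ratio	prevalence_pct	par_percent	sensitivity	specificity	rpb_ea	rpb_breast	rpb_ovarian	nb_ea	nb_breast	nb_ovarian
1.5	0.1	0.05	0.001	0.999	-0.000	-0.001	-0.001	-0.000	-0.000	-0.000
2	0.1	0.10	0.002	0.999	-0.000	-0.001	-0.001	-0.000	-0.000	-0.000
4	0.1	0.29	0.004	0.999	0.000	-0.000	-0.001	0.000	-0.000	-0.000
10	0.1	0.81	0.009	0.999	0.002	0.001	-0.000	0.000	0.000	-0.000
20	0.1	1.56	0.017	0.999	0.004	0.002	0.000	0.000	0.000	0.000
50	0.1	3.19	0.033	0.999	0.008	0.004	0.001	0.000	0.000	0.000
1.5	1	0.49	0.015	0.990	-0.004	-0.006	-0.008	-0.000	-0.000	-0.001
2	1	0.97	0.020	0.990	-0.002	-0.006	-0.008	0.000	-0.000	-0.001
4	1	2.81	0.038	0.990	0.002	-0.003	-0.007	0.000	-0.000	-0.001
10	1	7.61	0.085	0.991	0.015	0.004	-0.003	0.001	0.000	-0.001
20	1	13.93	0.148	0.991	0.031	0.014	0.001	0.001	0.001	0.000
50	1	26.33	0.271	0.993	0.063	0.033	0.010	0.002	0.002	0.002
1.5	10	4.70	0.142	0.900	-0.039	-0.065	-0.084	-0.002	-0.004	-0.013
2	10	8.94	0.180	0.901	-0.029	-0.059	-0.082	-0.001	-0.004	-0.013
4	10	22.54	0.303	0.902	0.003	-0.040	-0.073	0.000	-0.003	-0.012
10	10	46.05	0.514	0.904	0.058	-0.008	-0.057	0.002	-0.001	-0.009
20	10	63.92	0.675	0.906	0.100	0.017	-0.046	0.004	0.001	-0.007
50	10	81.79	0.836	0.907	0.141	0.041	-0.034	0.006	0.003	-0.005
1.5	30	12.90	0.390	0.701	-0.125	-0.200	-0.256	-0.005	-0.014	-0.041
2	30	22.80	0.460	0.702	-0.107	-0.189	-0.251	-0.004	-0.013	-0.040
4	30	46.84	0.628	0.703	-0.064	-0.163	-0.238	-0.003	-0.011	-0.038
10	30	72.43	0.807	0.705	-0.017	-0.136	-0.225	-0.001	-0.009	-0.036
20	30	84.69	0.893	0.706	0.005	-0.123	-0.219	0.000	-0.009	-0.035
50	30	93.44	0.954	0.707	0.021	-0.114	-0.215	0.001	-0.008	-0.034
1.5	70	25.71	0.777	0.301	-0.327	-0.486	-0.606	-0.013	-0.034	-0.096
2	70	40.89	0.823	0.301	-0.316	-0.480	-0.603	-0.013	-0.033	-0.096
4	70	67.46	0.902	0.302	-0.295	-0.467	-0.597	-0.012	-0.032	-0.095
10	70	86.14	0.958	0.303	-0.280	-0.459	-0.593	-0.011	-0.032	-0.094
20	70	92.92	0.979	0.303	-0.275	-0.456	-0.591	-0.011	-0.032	-0.094
50	70	97.13	0.991	0.303	-0.272	-0.454	-0.591	-0.011	-0.031	-0.094
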