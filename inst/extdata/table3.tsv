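construct	kcat_s	kcat_se	km_M	km_se	eff_printed	kd_atp_M	kd_atp_se	kd_trna_M	kd_trna_se	zn_ratio	zn_ratio_se
wt	5.3	0.1	65.4e-6	6.7e-6	8.1e4	28.0e-6	2.8e-6	62.5e-9	6.3e-9	0.93	0.01
Bt	6.6	0.7	139.4e-6	3.7e-6	4.7e4	39.5e-6	0.7e-6	91.0e-9	7.0e-9	0.05	0.01
Te	0.20	0.03	250.5e-6	4.0e-6	8.0e2	32.0e-6	4.2e-6	222e-9	5.6e-9	1.08	0.08
EQRS	1.5e-2	0.2e-2	284.6e-6	3.0e-6	53	35.5e-6	0.7e-6	385e-9	19e-9	1.09	0.05
dH4	8.5e-3	0.1e-3	441.5e-6	9.2e-6	19	28.0e-6	1.4e-6	499e-9	8.4e-9	1.00	0.05
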