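# kinwin thresholds v1
twin_gate	0.95
high_p2_min	412
iw_frac_cut_PO	0.8348306842
iw_frac_cut_D2	0.3439875605
iw_frac_cut_D3	0.1560124395
iw_frac_cut_D4	0.07601935038
iw_frac_cut_D5	0.05494125777
contig_frac_min	0.375
max_run_min	3.5
meta.se	0
meta.p0_cutoff	0
meta.window_size	1e+06
meta.n_sites	6e+05
meta.n_train	351
meta.train_accuracy	0.934472934472934
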