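sample,n_repeats,phase,n_trajectories,amplitude_nm,uncertainty_nm,r_dna_published_nm
6An0,0,,3496,149.7,0.2,105.4
6An1P,1,P,2728,149.1,0.2,104.1
6An2P,2,P,2354,149.7,0.2,105.4
6An3P,3,P,2904,149.6,0.2,105.2
6An4P,4,P,2604,146.5,0.2,98.5
6An6P,6,P,348,145.2,0.4,95.5
6An7P,7,P,431,140.4,0.4,84.1
6An4O,4,O,2990,151.2,0.2,108.6
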