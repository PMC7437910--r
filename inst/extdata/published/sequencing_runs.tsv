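run	reads_q0_millions	reads_q15_millions	yield_q0_gbp	yield_q15_gbp	mean_median_q0_bp	mean_q15_bp	median_q15_bp
Run1	880	565	66	28.815	75	51	52
Run2	778	546	58.3	28.938	75	53	55
Run3_1K	944	517	56.64	24.299	60	47	50
Run4_3K	805	400	48.3	18.8	60	47	47
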