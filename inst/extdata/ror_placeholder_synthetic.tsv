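key	value
# SYNTHETIC PLACEHOLDER configuration -- not the published ROR-C Cox
# coefficients, which must be transcribed from their original publication
# before clinical-style use. Layout: weight:<class> rows give the per-class
# correlation weights; tumor_size_weight, threshold_low, threshold_high,
# rescale_a, rescale_b are scalars.
weight:Basal	0.5
weight:Her2	0.3
weight:LumA	-0.8
weight:LumB	0.4
tumor_size_weight	0.2
threshold_low	0
threshold_high	0.6
rescale_a	1
rescale_b	0
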