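cohort	n_samples	comparator	ref_call	loss	neutral	gain
FOCUS	288	softctm_he2	loss	2066	23	1
FOCUS	288	softctm_he2	neutral	72	6662	74
FOCUS	288	softctm_he2	gain	0	22	2312
FOCUS	288	estimate	loss	1340	749	1
FOCUS	288	estimate	neutral	0	6808	0
FOCUS	288	estimate	gain	0	675	1659
FOCUS	288	infiniumpurify	loss	1622	466	2
FOCUS	288	infiniumpurify	neutral	19	6761	28
FOCUS	288	infiniumpurify	gain	0	458	1876
FOCUS	288	cp	loss	2034	55	1
FOCUS	288	cp	neutral	416	6008	384
FOCUS	288	cp	gain	0	43	2291
GRAMPIAN	74	softctm_he2	loss	474	15	0
GRAMPIAN	74	softctm_he2	neutral	6	1865	8
GRAMPIAN	74	softctm_he2	gain	0	14	504
GRAMPIAN	74	estimate	loss	363	126	0
GRAMPIAN	74	estimate	neutral	0	1878	1
GRAMPIAN	74	estimate	gain	1	118	399
GRAMPIAN	74	infiniumpurify	loss	456	33	0
GRAMPIAN	74	infiniumpurify	neutral	56	1760	63
GRAMPIAN	74	infiniumpurify	gain	2	26	490
GRAMPIAN	74	cp	loss	489	0	0
GRAMPIAN	74	cp	neutral	197	1455	227
GRAMPIAN	74	cp	gain	3	2	513
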