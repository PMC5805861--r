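variant_id	effect_allele	other_allele	weight	eaf
var01	C	T	0.102	0.201
var02	C	T	0.231	0.06
var03	G	T	0.114	0.239
var04	A	C	0.294	0.556
var05	C	A	0.128	0.269
var06	G	A	0.196	0.381
var07	A	G	0.214	0.079
var08	A	C	0.093	0.513
var09	T	G	0.199	0.241
var10	G	A	0.193	0.09
var11	A	C	0.289	0.507
var12	C	T	0.112	0.38
var13	G	T	0.455	0.189
var14	G	T	0.169	0.181
var15	G	A	0.159	0.221
var16	A	G	0.378	0.255
var17	A	G	0.077	0.439
var18	C	T	0.101	0.13
var19	C	T	0.121	0.113
var20	T	G	0.119	0.419
var21	T	G	0.711	0.317
var22	A	C	0.083	0.358
var23	G	A	0.412	0.206
var24	A	G	0.097	0.206
var25	T	C	0.431	0.553
var26	T	G	0.385	0.088
var27	C	T	0.358	0.319
var28	C	A	0.195	0.594
var29	A	G	0.101	0.191
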