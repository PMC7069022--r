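gene_id	microarray_log_fc	rnaseq_log_fc
CAMKV	1.47	1.73
CPNE7	1.38	2.75
GLRA2	1.52	2.80
HHIP	1.38	1.89
KCNH5	1.45	2.11
LGR5	1.26	2.38
TMEM131L	1.06	1.05
LRRC7	1.29	2.02
NME1	0	1.00
SLC30A3	1.10	4.06
SLC16A1	1.37	1.08
SLCO5A1	1.84	2.08
TMEM97	1.89	1.56
SLC44A5	1.42	1.33
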