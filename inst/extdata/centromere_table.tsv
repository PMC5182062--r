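chromosome	l_cbs_mb	r_cbs_mb	length_mb
1	13.98	23.24	36.32
2	9.81	14.85	25.51
3	9.98	20.32	31.52
4	12.23	18.34	31.72
5	10.37	17.39	27.47
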