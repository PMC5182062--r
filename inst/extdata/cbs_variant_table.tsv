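variant	count
canonical	109
1A	53
11C	8
13A	7
13C	2
14A	9
14C	4
15A	10
1A,11C	5
1A,13A	2
1A,13C	1
1A,14C	2
1A,15A	8
11C,13A	1
11C,13G	1
11C,14C	1
11C,15A	1
14A,15A	1
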