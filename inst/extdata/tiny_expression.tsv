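gene_id	s1	s2	s3	s4
gA	1.5	2.5	3.5	4.5
gB	5	5	6	6
gC	2	8	4	6
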