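cell_adhesion	BP	gA	gB
nucleus	CC	gB	gC
kinase_activity	MF	gA	gC
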