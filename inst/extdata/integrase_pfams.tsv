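namespace	id	description
pfam	PF00589	Phage integrase family (tyrosine recombinase)
pfam	PF02899	Phage integrase, N-terminal SAM-like domain
pfam	PF00239	Resolvase / serine recombinase domain
pfam	PF07508	Recombinase
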