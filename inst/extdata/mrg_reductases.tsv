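namespace	id	description
ko	K00537	arsC; arsenate reductase (synthetic default)
ko	K00520	merA; mercuric reductase (synthetic default)
ko	K19784	chromate reductase, NAD(P)H-dependent (synthetic default)
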