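namespace	id	description
ko	K15726	czcA; cobalt/zinc/cadmium efflux RND transporter (synthetic default)
ko	K07787	cusA; copper/silver efflux RND transporter (synthetic default)
ko	K07240	chrA; chromate transporter (synthetic default)
ko	K17686	copA; Cu+ exporting P-type ATPase (synthetic default)
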