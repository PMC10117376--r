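variant	kind	position	provenance
p.Q178E	missense	178	inherited
p.K228E	missense	228	de_novo
p.W271C	missense	271	de_novo
p.W271R	missense	271	de_novo
p.V356M	missense	356	inherited
p.N374H	missense	374	de_novo
p.K389E	missense	389	de_novo
p.Q418R	missense	418	inherited
p.P542R	missense	542	inherited
p.A136Pfs*80	frameshift	136	de_novo
p.S351*	nonsense	351	de_novo
p.N394*	nonsense	394	synthetic
p.S568*	nonsense	568	synthetic
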