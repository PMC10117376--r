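variant	interactor	class
p.K228E	GATAD2B	retained
p.W271C	GATAD2B	retained
p.W271R	GATAD2B	retained
p.N374H	GATAD2B	retained
p.K389E	GATAD2B	retained
p.Q178E	GATAD2B	retained
p.V356M	GATAD2B	retained
p.P542R	GATAD2B	retained
p.Q418R	GATAD2B	abolished
p.A136Pfs*80	GATAD2B	abolished
p.S351*	GATAD2B	abolished
p.N394*	GATAD2B	abolished
p.S568*	GATAD2B	retained
p.K228E	BCOR	retained
p.W271C	BCOR	retained
p.W271R	BCOR	reduced
p.N374H	BCOR	retained
p.K389E	BCOR	retained
p.Q178E	BCOR	retained
p.V356M	BCOR	retained
p.P542R	BCOR	retained
p.Q418R	BCOR	reduced
p.A136Pfs*80	BCOR	abolished
p.S351*	BCOR	abolished
p.N394*	BCOR	abolished
p.S568*	BCOR	retained
p.K228E	ADNP	abolished
p.W271C	ADNP	abolished
p.W271R	ADNP	retained
p.N374H	ADNP	abolished
p.K389E	ADNP	abolished
p.Q178E	ADNP	retained
p.V356M	ADNP	retained
p.P542R	ADNP	retained
p.Q418R	ADNP	abolished
p.A136Pfs*80	ADNP	abolished
p.S351*	ADNP	abolished
p.N394*	ADNP	retained
p.S568*	ADNP	retained
p.K228E	NR2F1	reduced
p.W271C	NR2F1	reduced
p.W271R	NR2F1	reduced
p.N374H	NR2F1	reduced
p.K389E	NR2F1	abolished
p.Q178E	NR2F1	retained
p.V356M	NR2F1	retained
p.P542R	NR2F1	retained
p.Q418R	NR2F1	reduced
p.A136Pfs*80	NR2F1	abolished
p.S351*	NR2F1	abolished
p.N394*	NR2F1	reduced
p.S568*	NR2F1	retained
p.K228E	NR2F2	retained
p.W271C	NR2F2	reduced
p.W271R	NR2F2	reduced
p.N374H	NR2F2	reduced
p.K389E	NR2F2	abolished
p.Q178E	NR2F2	retained
p.V356M	NR2F2	retained
p.P542R	NR2F2	retained
p.Q418R	NR2F2	reduced
p.A136Pfs*80	NR2F2	abolished
p.S351*	NR2F2	abolished
p.N394*	NR2F2	reduced
p.S568*	NR2F2	retained
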