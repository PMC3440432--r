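# Reaction table (SYNTHETIC transcription; see synthetic_model/README.md).
# Reversible rows ("<->") are expanded on load into an association/dissociation
# pair sharing reversible_pair_id = reaction_id; k_fwd_id drives lhs->rhs.
reaction_id	lhs	arrow	rhs	k_fwd_id	k_rev_id	submodel
R01	TF + VII	<->	TF=VII	k2	k1	base_extrinsic
R02	TF + VIIa	<->	TF=VIIa	k4	k3	base_extrinsic
R03	TF=VIIa + VII	->	TF=VIIa + VIIa	k5		base_extrinsic
R04	Xa + VII	->	Xa + VIIa	k6		base_extrinsic
R05	IIa + VII	->	IIa + VIIa	k7		base_extrinsic
R06	TF=VIIa + X	<->	TF=VIIa=X	k9	k8	base_extrinsic
R07	TF=VIIa=X	->	TF=VIIa=Xa	k10		base_extrinsic
R08	TF=VIIa + Xa	<->	TF=VIIa=Xa	k12	k11	base_extrinsic
R09	TF=VIIa + IX	<->	TF=VIIa=IX	k14	k13	base_extrinsic
R10	TF=VIIa=IX	->	TF=VIIa + IXa	k15		base_extrinsic
R11	Xa + II	->	Xa + IIa	k16		base_extrinsic
R12	IIa + VIII	->	IIa + VIIIa	k17		base_extrinsic
R13	VIIIa + IXa	<->	IXa=VIIIa	k19	k18	base_extrinsic
R14	IXa=VIIIa + X	<->	IXa=VIIIa=X	k21	k20	base_extrinsic
R15	IXa=VIIIa=X	->	IXa=VIIIa + Xa	k22		base_extrinsic
R16	VIIIa	<->	VIIIa1=L + VIIIa2	k24	k23	base_extrinsic
R17	IXa=VIIIa=X	->	VIIIa1=L + VIIIa2 + X + IXa	k25		base_extrinsic
R18	IXa=VIIIa	->	VIIIa1=L + VIIIa2 + IXa	k25		base_extrinsic
R19	IIa + V	->	IIa + Va	k26		base_extrinsic
R20	Xa + Va	<->	Xa=Va	k28	k27	base_extrinsic
R21	Xa=Va + II	<->	Xa=Va=II	k30	k29	base_extrinsic
R22	Xa=Va=II	->	Xa=Va + mIIa	k31		base_extrinsic
R23	mIIa + Xa=Va	->	IIa + Xa=Va	k32		base_extrinsic
R24	Xa + TFPI	<->	Xa=TFPI	k34	k33	base_extrinsic
R25	TF=VIIa=Xa + TFPI	<->	TF=VIIa=Xa=TFPI	k36	k35	base_extrinsic
R26	TF=VIIa + Xa=TFPI	->	TF=VIIa=Xa=TFPI	k37		base_extrinsic
R27	Xa + AT	->	Xa=AT	k38		base_extrinsic
R28	mIIa + AT	->	mIIa=AT	k39		base_extrinsic
R29	IXa + AT	->	IXa=AT	k40		base_extrinsic
R30	IIa + AT	->	IIa=AT	k41		base_extrinsic
R31	TF=VIIa + AT	->	TF=VIIa=AT	k42		base_extrinsic
R32	IIa + Tm	<->	IIa=Tm	kpc01	kpc02	pc_pathway
R33	mIIa + Tm	<->	mIIa=Tm	kpc03	kpc04	pc_pathway
R34	IIa=Tm + PC	<->	IIa=Tm=PC	kpc05	kpc06	pc_pathway
R35	IIa=Tm=PC	->	IIa=Tm + APC	kpc07		pc_pathway
R36	mIIa=Tm + PC	<->	mIIa=Tm=PC	kpc08	kpc09	pc_pathway
R37	mIIa=Tm=PC	->	mIIa=Tm + APC	kpc10		pc_pathway
R38	IIa=Tm + AT	->	IIa=AT + Tm	kpc11		pc_pathway
R39	mIIa=Tm + AT	->	mIIa=AT + Tm	kpc12		pc_pathway
R40	APC + Va	<->	APC=Va	kpc13	kpc14	pc_pathway
R41	APC=Va	->	APC + Va5	kpc15		pc_pathway
R42	APC + Va5	<->	APC=Va5	kpc16	kpc17	pc_pathway
R43	APC=Va5	->	APC + Va53	kpc18		pc_pathway
R44	APC + VIIIa	<->	APC=VIIIa	kpc19	kpc20	pc_pathway
R45	APC=VIIIa	->	APC + VIIIai	kpc21		pc_pathway
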