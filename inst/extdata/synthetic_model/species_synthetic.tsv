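# Species table for the extrinsic coagulation cascade + protein C pathway model.
# SYNTHETIC transcription: base mechanism after Hockin et al. 2002 (J Biol Chem
# 277:18322); PC-pathway module is a literature-guided construction of this
# package (see synthetic_model/README.md).
# Notation: complexes joined with "=", active enzymes carry an "a" suffix.
# moieties: semicolon-separated moiety:count pairs (elementary protein content).
symbol	display_name	moieties	submodel
TF	tissue factor	TF:1	base_extrinsic
VII	factor VII zymogen	VII:1	base_extrinsic
TF=VII	TF-fVII complex	TF:1;VII:1	base_extrinsic
VIIa	factor VIIa	VII:1	base_extrinsic
TF=VIIa	extrinsic tenase	TF:1;VII:1	base_extrinsic
Xa	factor Xa	X:1	base_extrinsic
IIa	thrombin	II:1	base_extrinsic
X	factor X zymogen	X:1	base_extrinsic
TF=VIIa=X	extrinsic tenase-fX complex	TF:1;VII:1;X:1	base_extrinsic
TF=VIIa=Xa	extrinsic tenase-fXa complex	TF:1;VII:1;X:1	base_extrinsic
IX	factor IX zymogen	IX:1	base_extrinsic
TF=VIIa=IX	extrinsic tenase-fIX complex	TF:1;VII:1;IX:1	base_extrinsic
IXa	factor IXa	IX:1	base_extrinsic
II	prothrombin	II:1	base_extrinsic
VIII	factor VIII zymogen	VIII:1;VIII2:1	base_extrinsic
VIIIa	factor VIIIa	VIII:1;VIII2:1	base_extrinsic
IXa=VIIIa	intrinsic tenase	IX:1;VIII:1;VIII2:1	base_extrinsic
IXa=VIIIa=X	intrinsic tenase-fX complex	IX:1;VIII:1;VIII2:1;X:1	base_extrinsic
VIIIa1=L	fVIIIa A1 subunit (membrane-bound)	VIII:1	base_extrinsic
VIIIa2	fVIIIa A2 subunit	VIII2:1	base_extrinsic
V	factor V zymogen	V:1	base_extrinsic
Va	factor Va	V:1	base_extrinsic
Xa=Va	prothrombinase	X:1;V:1	base_extrinsic
Xa=Va=II	prothrombinase-prothrombin complex	X:1;V:1;II:1	base_extrinsic
mIIa	meizothrombin	II:1	base_extrinsic
TFPI	tissue factor pathway inhibitor	TFPI:1	base_extrinsic
Xa=TFPI	fXa-TFPI complex	X:1;TFPI:1	base_extrinsic
TF=VIIa=Xa=TFPI	quaternary TFPI complex	TF:1;VII:1;X:1;TFPI:1	base_extrinsic
AT	antithrombin	AT:1	base_extrinsic
Xa=AT	fXa-antithrombin complex	X:1;AT:1	base_extrinsic
mIIa=AT	meizothrombin-antithrombin complex	II:1;AT:1	base_extrinsic
IXa=AT	fIXa-antithrombin complex	IX:1;AT:1	base_extrinsic
IIa=AT	thrombin-antithrombin complex	II:1;AT:1	base_extrinsic
TF=VIIa=AT	extrinsic tenase-antithrombin complex	TF:1;VII:1;AT:1	base_extrinsic
Tm	thrombomodulin (soluble)	Tm:1	pc_pathway
PC	protein C zymogen	PC:1	pc_pathway
APC	activated protein C	PC:1	pc_pathway
IIa=Tm	thrombin-thrombomodulin complex	II:1;Tm:1	pc_pathway
mIIa=Tm	meizothrombin-thrombomodulin complex	II:1;Tm:1	pc_pathway
IIa=Tm=PC	PC activation complex (IIa)	II:1;Tm:1;PC:1	pc_pathway
mIIa=Tm=PC	PC activation complex (mIIa)	II:1;Tm:1;PC:1	pc_pathway
APC=Va	APC-fVa complex	PC:1;V:1	pc_pathway
Va5	fVa cleaved at Arg506 (inactive cofactor)	V:1	pc_pathway
APC=Va5	APC-fVa5 complex	PC:1;V:1	pc_pathway
Va53	fVa cleaved at Arg506+Arg306 (inert)	V:1	pc_pathway
APC=VIIIa	APC-fVIIIa complex	PC:1;VIII:1;VIII2:1	pc_pathway
VIIIai	APC-inactivated fVIIIa	VIII:1;VIII2:1	pc_pathway
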