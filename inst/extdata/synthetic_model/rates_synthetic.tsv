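# Rate constant table (SYNTHETIC transcription; see synthetic_model/README.md).
# All bimolecular constants converted to per-nanomolar units
# (1 M^-1 s^-1 = 1e-9 nM^-1 s^-1).  Base ids follow the k1..k42 numbering of
# Hockin et al. 2002 Table; kpc* are this package's literature-guided PC-module
# choices (synthetic; not taken from a published table).
k_id	value	units	source_note
k1	3.1e-3	per_second	HM2002 k1 TF/fVII off
k2	3.2e-3	per_nanomolar_per_second	HM2002 k2 TF/fVII on (3.2e6 /M/s)
k3	3.1e-3	per_second	HM2002 k3 TF/fVIIa off
k4	2.3e-2	per_nanomolar_per_second	HM2002 k4 TF/fVIIa on (2.3e7 /M/s)
k5	4.4e-4	per_nanomolar_per_second	HM2002 k5 fVII activation by TF=VIIa (4.4e5 /M/s)
k6	1.3e-2	per_nanomolar_per_second	HM2002 k6 fVII activation by fXa (1.3e7 /M/s)
k7	2.3e-5	per_nanomolar_per_second	HM2002 k7 fVII activation by IIa (2.3e4 /M/s)
k8	1.05	per_second	HM2002 k8 TF=VIIa=X off
k9	2.5e-2	per_nanomolar_per_second	HM2002 k9 TF=VIIa + fX on (2.5e7 /M/s)
k10	6.0	per_second	HM2002 k10 fX activation within TF=VIIa=X
k11	19.0	per_second	HM2002 k11 TF=VIIa=Xa off
k12	2.2e-2	per_nanomolar_per_second	HM2002 k12 TF=VIIa + fXa on (2.2e7 /M/s)
k13	2.4	per_second	HM2002 k13 TF=VIIa=IX off
k14	1.0e-2	per_nanomolar_per_second	HM2002 k14 TF=VIIa + fIX on (1.0e7 /M/s)
k15	1.8	per_second	HM2002 k15 fIX activation within TF=VIIa=IX
k16	7.5e-6	per_nanomolar_per_second	HM2002 k16 fII activation by free fXa (7.5e3 /M/s)
k17	2.0e-2	per_nanomolar_per_second	HM2002 k17 fVIII activation by IIa (2.0e7 /M/s)
k18	5.0e-3	per_second	HM2002 k18 IXa=VIIIa off
k19	1.0e-2	per_nanomolar_per_second	HM2002 k19 fVIIIa + fIXa on (1.0e7 /M/s)
k20	1.0e-3	per_second	HM2002 k20 IXa=VIIIa=X off
k21	1.0e-1	per_nanomolar_per_second	HM2002 k21 IXa=VIIIa + fX on (1.0e8 /M/s)
k22	8.2	per_second	HM2002 k22 fX activation within intrinsic tenase
k23	2.2e-5	per_nanomolar_per_second	HM2002 k23 fVIIIa subunit reassociation (2.2e4 /M/s)
k24	6.0e-3	per_second	HM2002 k24 fVIIIa A2 dissociation
k25	1.0e-3	per_second	HM2002 k25 intrinsic tenase decay via fVIIIa subunit loss
k26	2.0e-2	per_nanomolar_per_second	HM2002 k26 fV activation by IIa (2.0e7 /M/s)
k27	0.2	per_second	HM2002 k27 prothrombinase off
k28	4.0e-1	per_nanomolar_per_second	HM2002 k28 fXa + fVa on (4.0e8 /M/s)
k29	103.0	per_second	HM2002 k29 prothrombinase-fII off
k30	1.0e-1	per_nanomolar_per_second	HM2002 k30 prothrombinase + fII on (1.0e8 /M/s)
k31	63.5	per_second	HM2002 k31 meizothrombin release
k32	1.5e-2	per_nanomolar_per_second	HM2002 k32 mIIa conversion by prothrombinase (1.5e7 /M/s)
k33	3.6e-4	per_second	HM2002 k33 Xa=TFPI off
k34	9.0e-4	per_nanomolar_per_second	HM2002 k34 fXa + TFPI on (9.0e5 /M/s)
k35	1.1e-4	per_second	HM2002 k35 quaternary TFPI complex off
k36	3.2e-1	per_nanomolar_per_second	HM2002 k36 TF=VIIa=Xa + TFPI on (3.2e8 /M/s)
k37	5.0e-2	per_nanomolar_per_second	HM2002 k37 TF=VIIa + Xa=TFPI (5.0e7 /M/s)
k38	1.5e-6	per_nanomolar_per_second	HM2002 k38 AT inhibition of fXa (1.5e3 /M/s)
k39	7.1e-6	per_nanomolar_per_second	HM2002 k39 AT inhibition of mIIa (7.1e3 /M/s)
k40	4.9e-7	per_nanomolar_per_second	HM2002 k40 AT inhibition of fIXa (4.9e2 /M/s)
k41	7.1e-6	per_nanomolar_per_second	HM2002 k41 AT inhibition of IIa (7.1e3 /M/s)
k42	2.3e-7	per_nanomolar_per_second	HM2002 k42 AT inhibition of TF=VIIa (2.3e2 /M/s)
kpc01	1.0e-1	per_nanomolar_per_second	synthetic: IIa + Tm on (1e8 /M/s, Kd 0.5 nM)
kpc02	5.0e-2	per_second	synthetic: IIa=Tm off
kpc03	1.0e-1	per_nanomolar_per_second	synthetic: mIIa + Tm on
kpc04	5.0e-2	per_second	synthetic: mIIa=Tm off
kpc05	1.0e-2	per_nanomolar_per_second	synthetic: IIa=Tm + PC on (1e7 /M/s)
kpc06	65.0	per_second	synthetic: IIa=Tm=PC off (Km ~6.9 uM)
kpc07	3.5	per_second	synthetic: PC activation kcat (IIa=Tm)
kpc08	1.0e-2	per_nanomolar_per_second	synthetic: mIIa=Tm + PC on
kpc09	65.0	per_second	synthetic: mIIa=Tm=PC off
kpc10	3.5	per_second	synthetic: PC activation kcat (mIIa=Tm)
kpc11	1.42e-5	per_nanomolar_per_second	synthetic: AT inhibition of IIa=Tm (2x free IIa rate)
kpc12	1.42e-5	per_nanomolar_per_second	synthetic: AT inhibition of mIIa=Tm
kpc13	4.0e-3	per_nanomolar_per_second	synthetic: APC + fVa on (4e6 /M/s effective; no protein S cofactor)
kpc14	7.0e-1	per_second	synthetic: APC=Va off
kpc15	5.0e-1	per_second	synthetic: fVa Arg506 cleavage kcat
kpc16	4.0e-3	per_nanomolar_per_second	synthetic: APC + fVa5 on
kpc17	7.0e-1	per_second	synthetic: APC=Va5 off
kpc18	1.0e-1	per_second	synthetic: fVa5 Arg306 cleavage kcat
kpc19	4.0e-3	per_nanomolar_per_second	synthetic: APC + fVIIIa on
kpc20	7.0e-1	per_second	synthetic: APC=VIIIa off
kpc21	5.0e-1	per_second	synthetic: fVIIIa inactivation kcat
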