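hsa04001	TNF signaling pathway	AKT1	ATP1A1	CASP3	EGF	FILL04	FILL36	FILL37	FILL39	FILL40	INS	NFKBIA	PTGS1	TLR4	TNF
hsa04002	NF-kappa B signaling pathway	EGF	FILL05	FILL14	FILL23	FILL35	FILL37	HK1	HSPA2	NFKBIA	PLA2G2A	PTGS1
hsa04003	Natural killer cell mediated cytotoxicity	ACTB	FILL02	FILL18	FILL23	FILL34	ICAM1	PLA2G2A	PPARA	PPP3CA	PPP3R1	PRKCA	TNF	VEGFA
hsa04004	T cell receptor signaling pathway	BCL2L1	CASP3	CSNK2A1	CYP2C9	FILL06	FILL08	FILL11	FILL13	FILL20	FILL21	FILL27	FILL34	IL6	LCN2	NFKBIA	PLA2G2A	PPP3R1	TRPV1	VEGFA
hsa04005	Toll-like receptor signaling pathway	ATP1A1	FILL07	FILL12	FILL13	FILL17	FILL20	FILL27	FILL32	INS	LCN2	MAPK1	NFKBIA	PPARG	PTGS1	TLR4	TRPV1
hsa04006	NOD-like receptor signaling pathway	CSNK2B	FILL02	FILL08	FILL17	FILL22	FILL24	FILL25	FILL33	HSPA2	IL6	INS	LCN2	MAPK1	PPP3CA	PPP3R1	PRKCA	PTGS1	TNF	VEGFA
hsa04007	IL-17 signaling pathway	BCL2L1	EGF	FILL21	FILL23	FILL25	FILL26	FILL27	FILL29	FILL31	FILL32	FILL34	FILL36	HSPA2	ICAM1	IL6	INS	MAPK1	PPARA	PPARG	PPP3R1	PTGS1	TNF	VEGFA
hsa04008	Chemokine signaling pathway	ATP1A1	BCL2L1	CSNK2B	CYP2C9	EGF	FILL02	FILL03	FILL05	FILL07	FILL10	FILL17	FILL21	FILL26	FILL28	FILL29	FILL32	FILL36	HK1	HSPA2	INS	MAPK1	PPARG	PTGS1	PTGS2	TLR4	TNF	VEGFA
hsa04009	Leukocyte transendothelial migration	CSNK2B	EGF	FILL05	FILL15	FILL18	FILL26	FILL27	FILL32	FILL36	FILL37	PPP3R1	PRKCA	PTGS1	PTGS2	TNF
hsa04010	C-type lectin receptor signaling pathway	EGF	FILL01	FILL04	FILL08	FILL12	FILL19	FILL24	FILL30	FILL31	FILL36	INS	PIK3CG	PTGS2
hsa04011	Th17 cell differentiation	AKT1	BCL2L1	CSNK2A1	FILL06	FILL10	FILL12	FILL15	FILL21	FILL22	FILL25	FILL29	FILL35	IL1B	INS	MAPK1	NFKBIA	PIK3CG	PTGS1	TLR4	TNF	TRPV1
hsa04012	Fc epsilon RI signaling pathway	ATP1A1	BCL2L1	CSNK2B	FILL04	FILL19	FILL21	ICAM1	IL1B	MAPK1	NFKBIA	PPARG	PRKCA	PTGS2
hsa04013	Complement and coagulation cascades	ATP1A1	CASP3	CYP2C9	FILL11	FILL12	FILL22	FILL37	IL1B	LCN2	PPP3R1	PTGS2	TRPV1
hsa04014	JAK-STAT signaling pathway	AKT1	CYP2C9	FILL08	FILL15	FILL16	FILL21	FILL22	FILL33	FILL34	HK1	HSPA2	IL1B	IL6	LCN2	MAPK1	PLA2G2A	PPARA	PPP3R1	PTGS1	PTGS2	TLR4	VEGFA
hsa04015	AMPK signaling pathway	AKT1	CASP3	FILL03	FILL04	FILL07	FILL08	FILL13	FILL15	FILL17	FILL19	FILL26	FILL27	FILL28	FILL32	FILL33	FILL38	HSPA2	ICAM1	IL1B	IL6	LCN2	MAPK1	PPARG	PPP3R1	PTGS2	PTK2B	TLR4	TNF
hsa04016	cAMP signaling pathway	ATP1A1	CSNK2A1	CSNK2B	CYP2C9	EGF	FILL01	FILL04	FILL09	FILL11	FILL19	FILL32	HK1	IL1B	NFKBIA	PPARG	PTGS2
hsa04017	Arachidonic acid metabolism	CSNK2A1	CSNK2B	CYP2C9	EGF	FILL02	FILL04	FILL05	FILL06	FILL09	FILL12	FILL20	FILL29	FILL31	FILL40	IL1B	IL6	INS	LCN2	MAPK1	PLA2G2A	PPP3CA	PTGS1	PTGS2	TRPV1	VEGFA
hsa04018	Insulin signaling pathway	AKT1	CSNK2B	FILL01	FILL03	FILL10	FILL11	FILL12	FILL13	FILL16	FILL24	FILL26	FILL30	HK1	IL1B	LCN2	MAPK1	PPARA	PPP3CA	PRKCA	TNF	TRPV1
hsa04019	PPAR signaling pathway	ATP1A1	CASP3	CSNK2B	FILL08	FILL09	FILL10	FILL12	FILL16	FILL25	FILL26	FILL30	FILL36	FILL39	HSPA2	LCN2	PIK3CG	PPP3R1	PRKCA	PTGS1	PTK2B	TLR4	TNF
hsa04020	Glucagon signaling pathway	ACTB	AKT1	CASP3	CSNK2B	CYP2C9	EGF	FILL01	FILL10	FILL14	FILL15	FILL19	FILL22	FILL23	FILL24	FILL29	FILL31	FILL35	ICAM1	IL6	PIK3CG	PLA2G2A	PPARA	PPP3CA	PRKCA	PTK2B	TRPV1
hsa04021	Glycolysis / Gluconeogenesis	AKT1	CASP3	FILL07	FILL16	FILL21	FILL24	FILL28	FILL31	FILL37	FILL40	INS	LCN2	NFKBIA	PLA2G2A
hsa04022	Fatty acid metabolism	CASP3	CSNK2A1	CSNK2B	FILL17	FILL22	FILL24	FILL25	FILL29	FILL33	HSPA2	ICAM1	IL1B	IL6	MAPK1	PLA2G2A	PPARA	PPP3R1	PRKCA	PTK2B	TRPV1	VEGFA
hsa04023	Linoleic acid metabolism	AKT1	ATP1A1	BCL2L1	CASP3	CSNK2B	CYP2C9	FILL01	FILL02	FILL09	FILL10	FILL32	FILL35	FILL38	HSPA2	MAPK1	PLA2G2A	PPARA	PPARG	PPP3CA	PPP3R1	PTK2B	VEGFA
hsa04024	Purine metabolism	CASP3	CSNK2A1	FILL04	FILL07	FILL09	FILL10	FILL11	FILL14	FILL20	FILL29	IL1B	LCN2	MAPK1	PPARA	PPP3CA	PPP3R1	PTK2B	TLR4
hsa04025	Apoptosis	ATP1A1	FILL02	FILL03	FILL09	FILL12	FILL23	FILL29	FILL30	FILL34	FILL37	FILL38	FILL39	INS	LCN2	NFKBIA	PIK3CG	PLA2G2A	PPARA	PPP3CA	PTGS1	PTK2B	TLR4	TNF	VEGFA
hsa04026	Calcium signaling pathway	CASP3	CSNK2A1	CYP2C9	EGF	FILL11	FILL14	FILL22	FILL25	FILL28	FILL32	FILL36	FILL39	HSPA2	ICAM1	IL1B	INS	LCN2	MAPK1	NFKBIA	PIK3CG	PTGS1	PTGS2	PTK2B	TLR4	TNF	TRPV1
hsa04027	HIF-1 signaling pathway	ACTB	AKT1	FILL06	FILL22	FILL24	FILL30	ICAM1	LCN2	PIK3CG	PPARA	PTGS1	PTK2B
hsa04028	PI3K-Akt signaling pathway	AKT1	CYP2C9	FILL13	FILL15	FILL18	FILL20	FILL24	FILL30	HSPA2	INS	PRKCA	PTGS1	TLR4
hsa04029	MAPK signaling pathway	ACTB	AKT1	CASP3	FILL01	FILL08	FILL09	FILL11	FILL16	FILL17	FILL18	FILL20	FILL25	FILL33	FILL35	FILL38	IL6	LCN2	MAPK1	NFKBIA	PLA2G2A	PRKCA	PTGS2	PTK2B	TLR4	TNF
hsa04030	VEGF signaling pathway	ATP1A1	BCL2L1	CSNK2A1	CYP2C9	FILL04	FILL07	FILL11	FILL18	FILL24	FILL32	FILL38	FILL39	IL6	INS	LCN2	PPARG	PPP3CA	PRKCA	TNF	TRPV1
hsa04031	p53 signaling pathway	AKT1	CYP2C9	FILL02	FILL07	FILL16	FILL21	FILL33	FILL35	MAPK1	PPARG	PPP3CA	PTGS1	PTK2B	TLR4	TNF
hsa04032	Oxidative phosphorylation	ATP1A1	FILL05	FILL16	FILL19	FILL29	HK1	HSPA2	IL1B	INS	PRKCA	PTGS1	PTK2B
hsa04033	Ferroptosis	CASP3	CYP2C9	EGF	FILL06	FILL19	FILL27	FILL29	FILL30	FILL33	FILL34	FILL36	FILL39	ICAM1	INS	LCN2	MAPK1	PLA2G2A	PPP3R1	PRKCA	PTGS2	TNF
hsa04034	Fluid shear stress and atherosclerosis	AKT1	BCL2L1	FILL05	FILL10	FILL13	FILL19	FILL20	FILL31	FILL36	FILL40	HSPA2	IL1B	MAPK1	TLR4	TRPV1
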