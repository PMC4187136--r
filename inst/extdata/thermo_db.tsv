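# protocean-thermodb v1.0 | standard-state Gibbs energies of formation at 298.15 K, 1 bar
# formula tokens are element-count pairs; solids carry waters of hydration explicitly
# solids with 'derived:' sources are back-computed from the cited solubility product
# using the aqueous ion values in this table, so the cited pKsp is reproduced exactly
name	formula	charge	phase_class	dGf_kJ_per_mol	source
H2O(l)	H2 O1	0	solvent	-237.140	CODATA 1989
H+	H1	1	aqueous	0.000	convention
OH-	O1 H1	-1	aqueous	-157.240	NBS 1982 (pKw 14.00)
Na+	Na1	1	aqueous	-261.905	CODATA 1989
Cl-	Cl1	-1	aqueous	-131.228	CODATA 1989
Mg+2	Mg1	2	aqueous	-454.800	NBS 1982
Ca+2	Ca1	2	aqueous	-553.580	NBS 1982
H3PO4(aq)	H3 P1 O4	0	aqueous	-1142.540	NBS 1982 (pKa1 2.15)
H2PO4-	H2 P1 O4	-1	aqueous	-1130.280	NBS 1982 (pKa2 7.21)
HPO4-2	H1 P1 O4	-2	aqueous	-1089.150	NBS 1982 (pKa3 12.34)
PO4-3	P1 O4	-3	aqueous	-1018.700	NBS 1982
NH4+	N1 H4	1	aqueous	-79.310	NBS 1982 (pKa 9.25)
NH3(aq)	N1 H3	0	aqueous	-26.500	NBS 1982
H2S(aq)	H2 S1	0	aqueous	-27.830	NBS 1982 (pKa1 6.99)
HS-	H1 S1	-1	aqueous	12.080	NBS 1982
H2(aq)	H2	0	aqueous	17.570	NBS 1982
O2(aq)	O2	0	aqueous	16.540	NBS 1982
N2(aq)	N2	0	aqueous	18.190	NBS 1982
HNO3(aq)	H1 N1 O3	0	aqueous	-111.250	approx. (NBS NO3- value); inactive by default
H3PO3(aq)	H3 P1 O3	0	aqueous	-856.900	approx. NBS 1982; inactive by default (P frozen +5)
H2PO3-	H2 P1 O3	-1	aqueous	-846.600	approx. NBS 1982; inactive by default (P frozen +5)
HPO3-2	H1 P1 O3	-2	aqueous	-810.400	approx. NBS 1982; inactive by default (P frozen +5)
H3PO2(aq)	H3 P1 O2	0	aqueous	-523.500	approx. NBS 1982; inactive by default (P frozen +5)
H2PO2-	H2 P1 O2	-1	aqueous	-512.100	approx. NBS 1982; inactive by default (P frozen +5)
N2(g)	N2	0	gas	0.000	reference state
H2(g)	H2	0	gas	0.000	reference state
O2(g)	O2	0	gas	0.000	reference state
H(g)	H1	0	gas	203.250	NBS 1982; inactive by default
H2O(g)	H2 O1	0	gas	-228.582	CODATA 1989
NH3(g)	N1 H3	0	gas	-16.450	NBS 1982
HCl(g)	H1 Cl1	0	gas	-95.300	CODATA 1989
Struvite	Mg1 N1 H16 P1 O10	0	solid	-3047.571	derived: pKsp 12.60 (Taylor et al. 1963)
Hydroxyapatite	Ca5 P3 O13 H1	0	solid	-6315.729	derived: pKsp 58.60 (within reported 57.5-59.6 range)
Monetite	Ca1 H1 P1 O4	0	solid	-1682.115	derived: pKsp 6.90 (McDowell et al.)
Brushite	Ca1 H5 P1 O6	0	solid	-2154.626	derived: pKsp 6.59 (Gregory et al. 1970)
Whitlockite	Ca3 P2 O8	0	solid	-3863.216	derived: pKsp 28.92 (beta-TCP, Gregory et al. 1974)
Farringtonite	Mg3 P2 O8	0	solid	-3542.788	derived: pKsp 24.70 (mid-range of reported 23.3-25.2)
Ca(H2PO4)2(s)	Ca1 H4 P2 O8	0	solid	-2819.277	derived: pKsp 0.90 (highly soluble; approx.)
Ca(H2PO4)2:H2O(s)	Ca1 H6 P2 O9	0	solid	-3057.787	derived: pKsp 1.14 (MCPM)
Ca2P2O7(s)	Ca2 P2 O7	0	solid	-3132.600	Robie & Hemingway 1995
Mg2P2O7(s)	Mg2 P2 O7	0	solid	-2902.900	Robie & Hemingway 1995
CaHPO3(s)	Ca1 H1 P1 O3	0	solid	-1402.224	derived: pKsp 6.70 approx.; inactive by default (P frozen +5)
NaH2PO4(s)	Na1 H2 P1 O4	0	solid	-1380.769	derived: log K_dis +2.00 (highly soluble salt)
Na2HPO4(s)	Na2 H1 P1 O4	0	solid	-1604.398	derived: log K_dis +1.50 (highly soluble salt)
Lime	Ca1 O1	0	solid	-603.300	Robie & Hemingway 1995
Portlandite	Ca1 O2 H2	0	solid	-898.312	derived: pKsp 5.30 (cf. Robie)
CaMgO2(s)	Ca1 Mg1 O2	0	solid	-1173.000	approx. (oxide sum)
Periclase	Mg1 O1	0	solid	-569.310	Robie & Hemingway 1995
Brucite	Mg1 O2 H2	0	solid	-833.495	derived: pKsp 11.25 (cf. Robie)
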