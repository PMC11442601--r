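id	reactants	products	k	k_units	kind	band_nm	provenance
1	H2O	HO. + H+ + e-	1	rel_weight	anodic	NA	water oxidation, first electron transfer; channel weight relative to unit water activity
2	HO. + H2O	H2O2 + H+ + e-	5e9	M-1_weight	anodic	NA	assumed; surface reoxidation of adsorbed HO. toward O2 on steel, second electron transfer
3	H2O2	HO2. + H+ + e-	2e3	M-1_weight	anodic	NA	assumed; third electron transfer of the water-oxidation sequence via peroxide intermediate
4	2 H2O	O2 + 4 H+ + 4 e-	20	rel_weight	anodic	NA	assumed; lumped fast surface conversion of adsorbed ROS intermediates to ground-state 3O2 (net 4-electron water oxidation), the dominant anodic channel on steel; the HO. escape channel (reaction 1) carries only a small fraction
5a	HO. + HO2.	1O2 + H2O	6.6e9	M-1 s-1	bulk	NA	Buxton et al. 1988 radical compilation (rate); singlet-oxygen product branch assumed
5b	2 HO.	H2O2	5.5e9	M-1 s-1	bulk	NA	Buxton et al. 1988 radical compilation
6	2 HO2.	1O2 + H2O2	8.3e5	M-1 s-1	bulk	NA	Bielski et al. 1985 HO2/O2- compilation (rate); singlet-oxygen branch assumed
7	HO2. + O2.- + H2O	1O2 + H2O2 + OH-	9.7e7	M-1 s-1	bulk	NA	Bielski et al. 1985 HO2/O2- compilation (rate); singlet-oxygen branch assumed
8	1O2	O2	2.9e5	s-1	emission	1278	singlet oxygen solvent quenching / monomolecular decay in water, lifetime ~3.4 us
9	2 1O2	2 O2	1e4	M-1 s-1	emission	634	assumed; bimolecular (dimol) singlet-oxygen decay, red emission
10	H2O2	HO2. + H+ + e-	2e3	M-1_weight	anodic	NA	electrooxidation of bulk-supplied hydrogen peroxide; weight assumed
12	O2.- + H2O2	HO. + OH- + O2	1e4	M-1 s-1	bulk	NA	assumed; effective trace-iron-catalysed Haber-Weiss constant (the uncatalysed value 0.13 of Weinstein & Bielski 1979 is dynamically inert; override via k_overrides to restore it)
13	HO. + H2O2	HO2. + H2O	2.7e7	M-1 s-1	bulk	NA	Buxton et al. 1988 radical compilation
14	BSA	BSA. + H+ + e-	1	M-1_weight	anodic	NA	assumed; direct anodic electrooxidation of accumulated protein with proton abstraction
15	BSA + HO.	BSA. + H2O	8e10	M-1 s-1	bulk	NA	near-diffusion-limited HO. attack on serum albumin, radiolysis literature
16	BSA. + O2	BSAOO.	5e8	M-1 s-1	bulk	NA	typical carbon-centred radical + O2 peroxyl formation rate
17	BSAOO.	3RCOR* + 1O2 + BSAox	5e-2	s-1	bulk	NA	assumed; cumulative cyclization/dimerization + fragmentation of protein peroxyl radicals (Russell-type), slow kinetically limited step
18	3RCOR*	BSAox	1e4	s-1	emission	425	assumed; triplet carbonyl deactivation with 350-500 nm emission
19	Fe2+ + H2O2	Fe3+ + HO. + OH-	76	M-1 s-1	bulk	NA	Fenton reaction, ferrous channel
20	Fe3+ + H2O2	Fe2+ + HO2. + H+	1e-2	M-1 s-1	bulk	NA	Fenton-like ferric reduction by peroxide, slow
21	2 O2.- + 2 H+ + SOD	H2O2 + O2 + SOD	1e9	M-1 s-1	enzymatic	NA	superoxide dismutase, 2e9 per superoxide consumed i.e. 1e9 per catalytic event; kcat/KM regime
22	2 H2O2 + CAT	2 H2O + O2 + CAT	8.5e6	M-1 s-1	enzymatic	NA	catalase, 1.7e7 per H2O2 consumed i.e. 8.5e6 per catalytic event; kcat/KM regime
23	2 H2O + 2 e-	H2 + 2 OH-	1	rel_weight	cathodic	NA	water electroreduction to hydrogen; channel weight relative to unit water activity
24	2 H+ + 2 e-	H2	1e-3	rel_weight	cathodic	NA	proton reduction, negligible at pH 7.2; weight assumed
25	O2 + e-	O2.-	1e2	M-1_weight	cathodic	NA	dissolved oxygen electroreduction to superoxide; weight assumed
26	O2.- + 2 H+ + e-	H2O2	1e4	M-1_weight	cathodic	NA	superoxide electroreduction to peroxide; weight assumed
27	HO2. + H+ + e-	H2O2	1e4	M-1_weight	cathodic	NA	hydroperoxyl electroreduction to peroxide; weight assumed
28	H2O2 + e-	HO. + OH-	1e3	M-1_weight	cathodic	NA	peroxide electroreduction with hydroxyl radical intermediate; weight assumed
29	HO. + e-	OH-	1e4	M-1_weight	cathodic	NA	hydroxyl radical electroreduction; weight assumed
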