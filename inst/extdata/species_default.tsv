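id	display	charge	composition	macromolecule	excited	fixed	diffusion_coeff	protein_bound
H2O	H2O	0	H:2,O:1	FALSE	FALSE	TRUE	2.3e-9	FALSE
H+	H+	1	H:1	FALSE	FALSE	TRUE	9.3e-9	FALSE
OH-	OH-	-1	H:1,O:1	FALSE	FALSE	TRUE	5.3e-9	FALSE
e-	e-	-1		FALSE	FALSE	TRUE	0	FALSE
O2	3O2	0	O:2	FALSE	FALSE	FALSE	2.0e-9	FALSE
1O2	1O2	0	O:2	FALSE	TRUE	FALSE	2.0e-9	FALSE
HO.	HO.	0	H:1,O:1	FALSE	FALSE	FALSE	2.2e-9	FALSE
HO2.	HO2.	0	H:1,O:2	FALSE	FALSE	FALSE	1.0e-9	FALSE
O2.-	O2.-	-1	O:2	FALSE	FALSE	FALSE	1.75e-9	FALSE
H2O2	H2O2	0	H:2,O:2	FALSE	FALSE	FALSE	1.4e-9	FALSE
HO2-	HO2-	-1	H:1,O:2	FALSE	FALSE	FALSE	1.4e-9	FALSE
H2	H2	0	H:2	FALSE	FALSE	FALSE	4.5e-9	FALSE
Fe2+	Fe2+	2	Fe:1	FALSE	FALSE	FALSE	0.7e-9	TRUE
Fe3+	Fe3+	3	Fe:1	FALSE	FALSE	FALSE	0.6e-9	TRUE
BSA	BSA	0		TRUE	FALSE	FALSE	6.3e-11	TRUE
BSA.	BSA.	0		TRUE	FALSE	FALSE	6.3e-11	TRUE
BSAOO.	BSAOO.	0		TRUE	FALSE	FALSE	6.3e-11	TRUE
3RCOR*	3(R'COR'')*	0		TRUE	TRUE	FALSE	6.3e-11	TRUE
BSAox	BSA_ox	0		TRUE	FALSE	FALSE	6.3e-11	TRUE
SOD	SOD	0		TRUE	FALSE	FALSE	1.0e-10	TRUE
CAT	CAT	0		TRUE	FALSE	FALSE	5.0e-11	TRUE
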