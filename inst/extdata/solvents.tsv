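# solvent registry: dielectric constant, normal boiling point (deg C),
# number of non-hydrogen atoms per solvent molecule.  Handbook values;
# user-editable (load_solvents() accepts any file in this layout).
name	epsilon	bp_c	heavy_atoms
water	78.36	100.0	1
methanol	32.61	64.7	2
ethanol	24.55	78.2	3
propanol	20.52	97.2	4
isopropanol	19.26	82.3	4
butanol	17.33	117.7	5
isobutanol	16.78	107.9	5
sec-butanol	15.94	99.5	5
pentanol	15.13	137.9	6
hexanol	12.51	157.6	7
heptanol	11.32	176.4	8
octanol	9.86	195.2	9
nonanol	8.60	213.3	10
decanol	7.53	231.1	11
benzyl alcohol	12.46	205.3	8
m-cresol	12.44	202.2	8
methoxyethanol	17.20	124.1	5
acetonitrile	35.69	81.6	3
dimethyl sulfoxide	46.83	189.0	4
dimethylformamide	37.22	153.0	5
dimethylacetamide	37.78	165.1	6
methyl formamide	181.56	199.5	4
nitromethane	36.56	101.2	4
nitroethane	28.29	114.0	5
nitrobenzene	34.81	210.8	9
o-nitrotoluene	25.67	222.0	10
acetophenone	17.44	202.0	9
butanone	18.25	79.6	5
cyclohexanone	15.62	155.6	7
4-methyl-2-pentanone	12.89	116.5	7
pyridine	12.98	115.2	6
2-methylpyridine	9.95	129.4	7
benzonitrile	25.59	191.1	9
sulfolane	43.26	285.0	8
dichloroethane	10.13	83.5	4
o-dichlorobenzene	9.99	180.5	8
bromoethane	9.01	38.4	3
methylene chloride	8.93	39.6	3
tetrahydrofuran	7.43	66.0	5
aniline	6.89	184.1	7
acetic acid	6.25	117.9	4
ethyl acetate	5.99	77.1	6
chlorobenzene	5.69	131.7	7
bromobenzene	5.40	156.0	7
fluorobenzene	5.42	84.7	7
iodobenzene	4.55	188.3	7
chloroform	4.71	61.2	4
diethyl ether	4.24	34.5	5
carbon disulfide	2.61	46.2	3
triethylamine	2.38	89.0	7
toluene	2.37	110.6	7
benzene	2.27	80.1	6
xylene	2.27	139.0	8
carbon tetrachloride	2.23	76.7	5
cyclohexane	2.02	80.7	6
octane	1.94	125.6	8
heptane	1.91	98.4	7
hexane	1.88	68.7	6
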