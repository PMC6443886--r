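molecule	solvent	residue	position_index	phi	psi
homochiral	DMSO	Ala1	1	-61.9	132.4
homochiral	DMSO	V4n2	2	-148.7	-176.8
homochiral	DMSO	F4c4	4	-58.6	-13.8
homochiral	DMSO	L4n5	5	-117.6	-148.0
homochiral	DMSO	F4c7	7	62.3	3.1
homochiral	DMSO	L4n8	8	-168.7	-171.1
homochiral	DMSO	V4c10	10	57.0	3.4
homochiral	water	Ala1	1	-67.0	131.8
homochiral	water	V4n2	2	-136.4	-112.8
homochiral	water	F4c4	4	75.7	1.5
homochiral	water	L4n5	5	-155.0	175.3
homochiral	water	F4c7	7	68.2	-3.8
homochiral	water	L4n8	8	-152.0	-168.6
homochiral	water	V4c10	10	51.5	3.9
heterochiral	DMSO	Ala1	1	-64.3	1.1
heterochiral	DMSO	V4n2	2	143.2	-169.5
heterochiral	DMSO	F4c4	4	72.2	39.2
heterochiral	DMSO	L4n5	5	132.9	-163.6
heterochiral	DMSO	F4c7	7	75.8	24.8
heterochiral	DMSO	L4n8	8	142.8	-175.4
heterochiral	DMSO	V4c10	10	65.0	-13.3
heterochiral	water	Ala1	1	-97.4	19.5
heterochiral	water	V4n2	2	167.0	-168.5
heterochiral	water	F4c4	4	64.6	39.4
heterochiral	water	L4n5	5	131.4	-48.1
heterochiral	water	F4c7	7	71.6	37.5
heterochiral	water	L4n8	8	125.1	168.7
heterochiral	water	V4c10	10	-51.1	-34.1
homochiral_gly	DMSO	Ala1	1	-78.8	158.2
homochiral_gly	DMSO	G4n2	2	-146.2	-170.3
homochiral_gly	DMSO	F4c4	4	-58.2	2.8
homochiral_gly	DMSO	G4n5	5	-156.9	-142.0
homochiral_gly	DMSO	F4c7	7	72.9	24.1
homochiral_gly	DMSO	G4n8	8	154.2	-166.1
homochiral_gly	DMSO	V4c10	10	62.1	0.0
homochiral_gly	water	Ala1	1	-133.1	15.5
homochiral_gly	water	G4n2	2	-130.4	165.5
homochiral_gly	water	F4c4	4	-67.1	22.5
homochiral_gly	water	G4n5	5	172.3	-153.7
homochiral_gly	water	F4c7	7	65.0	37.4
homochiral_gly	water	G4n8	8	131.5	-153.5
homochiral_gly	water	V4c10	10	83.9	-15.2
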