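kind	atoms	condition	target	actual	delta_printed
bond	C1-C15	geostd	1.534	1.514	0.020
bond	C1-C12	geostd	1.530	1.548	-0.018
angle	C15-C1-N12	geostd	111.6	118.8	-7.2
torsion	C9-C10-C11-N12	geostd	210.9	143.3	67.6
torsion	C1-C15-N14-C13	geostd	37.2	-16.4	53.6
torsion	C1-C12-C13-N14	geostd	-6.5	31.8	-38.4
bond	C1-C15	qmr	1.551	1.521	0.031
bond	C1-C12	qmr	1.546	1.574	-0.028
angle	C15-C1-N12	qmr	112.9	117.9	-5.0
torsion	C9-C10-C11-N12	qmr	142.6	144.2	-1.6
torsion	C1-C15-N14-C13	qmr	-13.8	-16.2	2.4
torsion	C1-C12-C13-N14	qmr	27.0	30.4	-3.4
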