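kind	atoms	condition	target	actual	delta_printed
bond	C20-O4	geostd	1.419	1.394	0.025
bond	C19-O3	geostd	1.430	1.409	0.021
angle	C10-C7-N1	geostd	109.7	117.3	-7.6
angle	C4-C10-C7	geostd	109.0	115.7	-6.7
angle	C15-O3-C19	geostd	115.2	121.3	-6.1
torsion	C4-C10-C7-N1	geostd	58.0	-18.7	76.7
torsion	C1-C7-N1-C10	geostd	43.0	-13.1	56.1
torsion	C2-C10-C4-C7	geostd	35.8	-12.4	48.2
bond	C20-O4	qmr	1.434	1.419	0.015
bond	C19-O3	qmr	1.437	1.440	-0.003
angle	C10-C7-N1	qmr	111.7	113.9	-2.2
angle	C4-C10-C7	qmr	110.9	113.2	-2.4
angle	C15-O3-C19	qmr	112.6	113.9	-1.3
torsion	C4-C10-C7-N1	qmr	-50.7	-40.3	-10.4
torsion	C1-C7-N1-C10	qmr	-26.9	-27.9	1.0
torsion	C2-C10-C4-C7	qmr	-39.0	-27.7	11.4
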