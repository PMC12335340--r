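# Scalar J-coupling constants (Hz) between the protons listed in
# spin_systems.tsv.  Pairs not listed couple with J = 0.  Couplings between
# magnetically equivalent protons are omitted (they do not affect spectra).
metabolite	proton_i	proton_j	j_hz
NAA	H2	H3	3.861
NAA	H2	H3p	9.821
NAA	H3	H3p	-15.592
NAAG	H2	H3	4.412
NAAG	H2	H3p	9.515
NAAG	H3	H3p	-15.910
NAAG	H2g	H3g	7.330
NAAG	H2g	H3gp	4.650
NAAG	H3g	H3gp	-14.850
NAAG	H3g	H4g	6.410
NAAG	H3g	H4gp	8.410
NAAG	H3gp	H4g	8.480
NAAG	H3gp	H4gp	6.880
NAAG	H4g	H4gp	-15.920
Cho	H1a	H2a	3.140
Cho	H1a	H2b	6.979
Cho	H1b	H2a	7.011
Cho	H1b	H2b	3.168
GPC	H7a	H8a	3.140
GPC	H7a	H8b	6.979
GPC	H7b	H8a	7.011
GPC	H7b	H8b	3.168
Glu	H2	H3	7.331
Glu	H2	H3p	4.651
Glu	H3	H3p	-14.849
Glu	H3	H4	6.413
Glu	H3	H4p	8.406
Glu	H3p	H4	8.478
Glu	H3p	H4p	6.875
Glu	H4	H4p	-15.915
Gln	H2	H3	5.847
Gln	H2	H3p	6.500
Gln	H3	H3p	-14.504
Gln	H3	H4	9.165
Gln	H3	H4p	6.347
Gln	H3p	H4	6.324
Gln	H3p	H4p	9.209
Gln	H4	H4p	-15.371
mI	H1	H2	2.889
mI	H2	H3	3.006
mI	H3	H4	9.997
mI	H4	H5	9.485
mI	H5	H6	9.482
mI	H1	H6	9.998
Lac	H2	me1	6.933
Lac	H2	me2	6.933
Lac	H2	me3	6.933
GABA	H2a	H3a	7.350
GABA	H2a	H3b	7.350
GABA	H2b	H3a	7.350
GABA	H2b	H3b	7.350
GABA	H3a	H4a	7.300
GABA	H3a	H4b	7.300
GABA	H3b	H4a	7.300
GABA	H3b	H4b	7.300
GSH	H2	H3	6.340
GSH	H2	H3p	6.360
GSH	H3	H3p	-15.480
GSH	H3	H4	6.700
GSH	H3	H4p	7.600
GSH	H3p	H4	7.600
GSH	H3p	H4p	6.700
GSH	H4	H4p	-15.920
GSH	H2c	H3c	7.090
GSH	H2c	H3cp	4.710
GSH	H3c	H3cp	-14.060
Ala	H2	me1	7.234
Ala	H2	me2	7.234
Ala	H2	me3	7.234
Glc	H1	H2	3.800
Glc	H2	H3	9.600
Glc	H3	H4	9.400
Glc	H4	H5	9.900
Glc	H5	H6a	1.500
Glc	H5	H6b	6.000
Glc	H6a	H6b	-12.100
Val	H2	H3	4.340
Val	H3	g1a	6.971
Val	H3	g1b	6.971
Val	H3	g1c	6.971
Val	H3	g2a	7.071
Val	H3	g2b	7.071
Val	H3	g2c	7.071
2HG	H2	H3	7.830
2HG	H2	H3p	4.300
2HG	H3	H3p	-14.280
2HG	H3	H4	10.580
2HG	H3	H4p	6.060
2HG	H3p	H4	5.580
2HG	H3p	H4p	10.850
2HG	H4	H4p	-15.000
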