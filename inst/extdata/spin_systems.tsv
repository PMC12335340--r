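# Proton spin-system constants for brain metabolites: chemical shifts (ppm),
# magnetic-equivalence groups and mutually uncoupled subsystems.
# Transcribed from the standard literature compendium of metabolite chemical
# shifts and J-coupling constants used for in vivo 1H MRS prior knowledge.
# Simplifications (documented in the package vignette): GPC keeps the
# trimethylammonium singlet plus the choline-like CH2-CH2 fragment (glycerol
# backbone omitted); GABA uses symmetrized vicinal couplings; only the
# alpha anomer of glucose is represented.
metabolite	proton	shift_ppm	group	subsystem
NAA	ac1	2.0080	ac	s1
NAA	ac2	2.0080	ac	s1
NAA	ac3	2.0080	ac	s1
NAA	H2	4.3817	H2	s2
NAA	H3	2.6727	H3	s2
NAA	H3p	2.4863	H3p	s2
NAAG	ac1	2.0420	ac	s1
NAAG	ac2	2.0420	ac	s1
NAAG	ac3	2.0420	ac	s1
NAAG	H2	4.6073	H2	s2
NAAG	H3	2.7212	H3	s2
NAAG	H3p	2.5194	H3p	s2
NAAG	H2g	4.1280	H2g	s3
NAAG	H3g	2.0490	H3g	s3
NAAG	H3gp	2.0760	H3gp	s3
NAAG	H4g	2.2590	H4g	s3
NAAG	H4gp	2.2460	H4gp	s3
Cho	tma1	3.1850	tma	s1
Cho	tma2	3.1850	tma	s1
Cho	tma3	3.1850	tma	s1
Cho	tma4	3.1850	tma	s1
Cho	tma5	3.1850	tma	s1
Cho	tma6	3.1850	tma	s1
Cho	tma7	3.1850	tma	s1
Cho	tma8	3.1850	tma	s1
Cho	tma9	3.1850	tma	s1
Cho	H1a	4.0540	H1	s2
Cho	H1b	4.0540	H1	s2
Cho	H2a	3.5010	H2	s2
Cho	H2b	3.5010	H2	s2
GPC	tma1	3.2120	tma	s1
GPC	tma2	3.2120	tma	s1
GPC	tma3	3.2120	tma	s1
GPC	tma4	3.2120	tma	s1
GPC	tma5	3.2120	tma	s1
GPC	tma6	3.2120	tma	s1
GPC	tma7	3.2120	tma	s1
GPC	tma8	3.2120	tma	s1
GPC	tma9	3.2120	tma	s1
GPC	H7a	4.3120	H7	s2
GPC	H7b	4.3120	H7	s2
GPC	H8a	3.6590	H8	s2
GPC	H8b	3.6590	H8	s2
Cr	me1	3.0270	me	s1
Cr	me2	3.0270	me	s1
Cr	me3	3.0270	me	s1
Cr	ch2a	3.9130	ch2	s2
Cr	ch2b	3.9130	ch2	s2
Glu	H2	3.7433	H2	s1
Glu	H3	2.0375	H3	s1
Glu	H3p	2.1200	H3p	s1
Glu	H4	2.3378	H4	s1
Glu	H4p	2.3520	H4p	s1
Gln	H2	3.7530	H2	s1
Gln	H3	2.1290	H3	s1
Gln	H3p	2.1090	H3p	s1
Gln	H4	2.4320	H4	s1
Gln	H4p	2.4540	H4p	s1
mI	H1	3.5217	H1	s1
mI	H2	4.0538	H2	s1
mI	H3	3.5217	H3	s1
mI	H4	3.6144	H4	s1
mI	H5	3.2690	H5	s1
mI	H6	3.6144	H6	s1
Lac	H2	4.0974	H2	s1
Lac	me1	1.3142	me	s1
Lac	me2	1.3142	me	s1
Lac	me3	1.3142	me	s1
GABA	H2a	2.2840	H2	s1
GABA	H2b	2.2840	H2	s1
GABA	H3a	1.8890	H3	s1
GABA	H3b	1.8890	H3	s1
GABA	H4a	3.0128	H4	s1
GABA	H4b	3.0128	H4	s1
GSH	H2	3.7690	H2	s1
GSH	H3	2.1590	H3	s1
GSH	H3p	2.1460	H3p	s1
GSH	H4	2.5100	H4	s1
GSH	H4p	2.5600	H4p	s1
GSH	H2c	4.5608	H2c	s2
GSH	H3c	2.9264	H3c	s2
GSH	H3cp	2.9747	H3cp	s2
GSH	H2ga	3.7690	H2g	s3
GSH	H2gb	3.7690	H2g	s3
Gly	H2a	3.5480	H2	s1
Gly	H2b	3.5480	H2	s1
Ala	H2	3.7746	H2	s1
Ala	me1	1.4667	me	s1
Ala	me2	1.4667	me	s1
Ala	me3	1.4667	me	s1
Glc	H1	5.2160	H1	s1
Glc	H2	3.5190	H2	s1
Glc	H3	3.6980	H3	s1
Glc	H4	3.3950	H4	s1
Glc	H5	3.8220	H5	s1
Glc	H6a	3.8260	H6a	s1
Glc	H6b	3.7490	H6b	s1
Val	H2	3.5953	H2	s1
Val	H3	2.2577	H3	s1
Val	g1a	1.0271	g1	s1
Val	g1b	1.0271	g1	s1
Val	g1c	1.0271	g1	s1
Val	g2a	0.9764	g2	s1
Val	g2b	0.9764	g2	s1
Val	g2c	0.9764	g2	s1
2HG	H2	4.0200	H2	s1
2HG	H3	1.8250	H3	s1
2HG	H3p	1.9750	H3p	s1
2HG	H4	2.2210	H4	s1
2HG	H4p	2.2720	H4p	s1
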