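label	n	Kd_uM	dH	minus_TdS	dG	T	note
PDZ3/KKETAV_pH7.5	0.99	1.5	-9.8	1.8	-8.0	298.15	50 mM potassium phosphate pH 7.5, 25 C
PDZ3/KKETAV_pH6.0	1.00	0.45	-5.3	-3.4	-8.7	298.15	20 mM MES pH 6.0, 10 mM NaCl, 25 C
PDZ3/YKQTSV	0.80	1.0	-10.0	1.9	-8.1	298.15	pH 7.5
D7ct-PDZ3/YKQTSV	0.90	6.0	-3.4	-3.7	-7.1	298.15	pH 7.5
D10ct-PDZ3/KKETAV	0.90	3.6	-8.8	1.4	-7.4	298.15	pH 7.5
E334Q-PDZ3/KKETAV	1.09	2.9	-9.8	2.2	-7.6	298.15	pH 7.5
E401R-PDZ3/KKETAV	1.10	1.5	-9.2	1.2	-8.0	298.15	pH 7.5
Y397E-PDZ3/KKETAV	0.98	2.7	-7.4	-0.2	-7.6	298.15	pH 7.5
PDZ3/NYKQTSV	0.98	3.6	-8.6	1.2	-7.4	298.15	pH 6.8
P397-PDZ3/NYKQTSV	0.99	14.0	-8.8	2.2	-6.6	298.15	pH 6.8
D332P-PDZ3/KKETAV	1.05	16.0	-7.9	1.4	-6.5	298.15	pH 7.5
D332G-PDZ3/KKETAV	1.01	2.2	-8.7	1.0	-7.7	298.15	pH 7.5
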