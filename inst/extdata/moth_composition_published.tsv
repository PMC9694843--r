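species	size_bp	T_pct	C_pct	A_pct	G_pct	AT_pct	GC_pct	GT_pct	AT_skew	GC_skew
Gazalina chrysolopha	15474	36.4	16.0	39.6	8.0	76.0	24.0	44.4	0.043	-0.335
Deroca hyalina	15332	41.2	10.7	40.2	7.9	81.4	18.6	49.1	-0.012	-0.153
Phyllosphingia dissimilis	15260	40.7	10.9	41.0	7.4	81.7	18.3	48.1	0.005	-0.191
Menophra sp.	15250	39.9	11.3	41.0	7.8	80.9	19.1	47.7	0.013	-0.189
Numenes albofascia	15756	38.6	13.5	40.3	7.6	78.9	21.1	46.2	0.021	-0.281
Rhagastis albomarginatus	14231	40.5	11.7	40.3	7.5	80.8	19.2	48.0	-0.003	-0.217
Zeuzera pyrina	15324	39.1	13.2	39.8	7.9	78.9	21.1	47.0	0.009	-0.256
Psyra falcipennis	15489	39.3	11.1	41.8	7.8	81.1	18.9	47.1	0.031	-0.175
Zaranga tukuringra	15330	37.5	13.5	41.2	7.8	78.7	21.3	45.3	0.047	-0.265
Paralebeda femorata	15376	38.5	12.8	40.9	7.8	79.4	20.6	46.3	0.030	-0.247
Sphragifera sigillata	15377	41.3	10.8	40.3	7.6	81.6	18.4	48.9	-0.013	-0.176
Lassaba albidaria	15351	41.4	7.9	39.8	10.9	81.2	18.8	52.3	-0.020	0.165
Asota tortuosa	15385	40.7	11.9	39.9	7.5	80.6	19.4	48.2	-0.011	-0.227
Hyalinetta circumflexa	15607	41.0	11.1	40.6	7.3	81.6	18.4	48.3	-0.005	-0.211
Dolbina inexacta	15232	39.6	11.5	41.3	7.6	80.9	19.1	47.2	0.022	-0.200
Dolbina paraexacta	15220	39.8	11.2	41.4	7.6	81.2	18.8	47.4	0.020	-0.192
Olivenebula oberthueri	15457	39.8	12.4	39.9	7.9	79.7	20.3	47.7	0.000	-0.220
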