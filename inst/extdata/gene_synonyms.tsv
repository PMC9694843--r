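synonym	name	kind
cox1	cox1	PCG
coi	cox1	PCG
co1	cox1	PCG
coxi	cox1	PCG
cox2	cox2	PCG
coii	cox2	PCG
co2	cox2	PCG
coxii	cox2	PCG
cox3	cox3	PCG
coiii	cox3	PCG
co3	cox3	PCG
coxiii	cox3	PCG
atp6	atp6	PCG
atpase6	atp6	PCG
atp8	atp8	PCG
atpase8	atp8	PCG
cytb	cytb	PCG
cob	cytb	PCG
cyt b	cytb	PCG
nad1	nad1	PCG
nd1	nad1	PCG
nad2	nad2	PCG
nd2	nad2	PCG
nad3	nad3	PCG
nd3	nad3	PCG
nad4	nad4	PCG
nd4	nad4	PCG
nad4l	nad4l	PCG
nd4l	nad4l	PCG
nad5	nad5	PCG
nd5	nad5	PCG
nad6	nad6	PCG
nd6	nad6	PCG
rrnl	rrnL	rRNA
16s	rrnL	rRNA
l-rrna	rrnL	rRNA
lrrna	rrnL	rRNA
16s ribosomal rna	rrnL	rRNA
rrns	rrnS	rRNA
12s	rrnS	rRNA
s-rrna	rrnS	rRNA
srrna	rrnS	rRNA
12s ribosomal rna	rrnS	rRNA
trna	trnA	tRNA
trna-ala	trnA	tRNA
trnr	trnR	tRNA
trna-arg	trnR	tRNA
trnn	trnN	tRNA
trna-asn	trnN	tRNA
trnd	trnD	tRNA
trna-asp	trnD	tRNA
trnc	trnC	tRNA
trna-cys	trnC	tRNA
trne	trnE	tRNA
trna-glu	trnE	tRNA
trnq	trnQ	tRNA
trna-gln	trnQ	tRNA
trng	trnG	tRNA
trna-gly	trnG	tRNA
trnh	trnH	tRNA
trna-his	trnH	tRNA
trni	trnI	tRNA
trna-ile	trnI	tRNA
trnl1	trnL1	tRNA
trna-leu(cun)	trnL1	tRNA
trnl2	trnL2	tRNA
trna-leu(uur)	trnL2	tRNA
trnk	trnK	tRNA
trna-lys	trnK	tRNA
trnm	trnM	tRNA
trna-met	trnM	tRNA
trnf	trnF	tRNA
trna-phe	trnF	tRNA
trnp	trnP	tRNA
trna-pro	trnP	tRNA
trns1	trnS1	tRNA
trna-ser(agn)	trnS1	tRNA
trns2	trnS2	tRNA
trna-ser(ucn)	trnS2	tRNA
trnt	trnT	tRNA
trna-thr	trnT	tRNA
trnw	trnW	tRNA
trna-trp	trnW	tRNA
trny	trnY	tRNA
trna-tyr	trnY	tRNA
trnv	trnV	tRNA
trna-val	trnV	tRNA
cr	CR	control_region
d-loop	CR	control_region
control region	CR	control_region
a+t-rich region	CR	control_region
at-rich region	CR	control_region
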