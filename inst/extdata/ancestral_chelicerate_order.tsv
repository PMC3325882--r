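# ancestral chelicerate (horseshoe-crab-type) mitochondrial gene arrangement, v1
# circular order linearized at the 5' end of CO1; major strand = strand
# encoding 9 PCGs + 13 tRNAs; control region included as positional marker
gene	strand
CO1	major
CO2	major
trnK	major
trnD	major
ATP8	major
ATP6	major
CO3	major
trnG	major
ND3	major
trnA	major
trnR	major
trnN	major
trnS1	major
trnE	major
trnF	minor
ND5	minor
trnH	minor
ND4	minor
ND4L	minor
trnT	major
trnP	minor
ND6	major
CYTB	major
trnS2	major
ND1	minor
trnL1	minor
trnL2	minor
rrnL	minor
trnV	minor
rrnS	minor
CONTROL_REGION	major
trnI	major
trnQ	minor
trnM	major
ND2	major
trnW	major
trnC	minor
trnY	minor
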