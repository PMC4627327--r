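# Default list of potentially spurious genes: frequently mutated in cancer
# sequencing studies for reasons unrelated to tumor biology (very large,
# late-replicating or lowly expressed genes, olfactory receptors, mucins).
# Edit or replace this file to use a different exclusion list.
TTN
MUC16
MUC4
MUC5B
MUC12
OBSCN
SYNE1
SYNE2
NEB
RYR1
RYR2
RYR3
CSMD1
CSMD3
FLG
FLG2
LRP1B
LRP2
PCLO
USH2A
GPR98
DNAH5
DNAH7
DNAH9
DNAH11
PKHD1
PKHD1L1
HYDIN
FAT4
AHNAK
AHNAK2
HMCN1
MACF1
PLEC
CUBN
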