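gene_name
G3BP1
G3BP2
CAPRIN1
USP10
TIA1
TIAL1
FMR1
FXR1
FXR2
PABPC1
EIF4G1
EIF4G2
EIF4E
EIF3A
EIF3B
EIF3G
EIF4A1
EIF4A2
DDX3X
DDX6
ATXN2
ATXN2L
UBAP2L
PRRC2C
STAU1
PUM1
PUM2
LSM14A
TNRC6A
TNRC6B
ELAVL1
CPEB1
CPEB4
DCP1A
DCP2
EDC3
EDC4
XRN1
UPF1
MOV10
IGF2BP1
IGF2BP2
IGF2BP3
HNRNPA1
SYNCRIP
TARDBP
FUS
YBX1
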