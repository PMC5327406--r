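gene	strand
NARS	+
FECH	+
ONECUT2	-
ST8SIA3	+
WDR7	+
TXNL1	-
TCF4	-
CCDC68	+
RAB27B	+
DYNAP	-
C18orf54	+
STARD6	+
POLI	+
MBD2	-
DCC	+
MEX3C	-
ELAC1	-
SMAD4	+
ME2	-
MAPK4	-
SKA1	+
CXXC1	+
MBD1	-
MYO5B	-
ACAA2	-
LIPG	-
C18orf32	+
RPL17	-
DYM	+
SMAD7	+
CTIF	+
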