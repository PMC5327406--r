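gene	species	status	tier
NARS	duck	detected	annotation
FECH	duck	detected	annotation
ONECUT2	duck	detected	annotation
ST8SIA3	duck	detected	annotation
WDR7	duck	detected	annotation
TXNL1	duck	detected	annotation
TCF4	duck	detected	annotation
CCDC68	duck	detected	annotation
RAB27B	duck	detected	annotation
DYNAP	duck	detected	annotation
C18orf54	duck	detected	annotation
STARD6	duck	detected	annotation
POLI	duck	detected	annotation
MBD2	duck	detected	annotation
DCC	duck	detected	annotation
MEX3C	duck	detected	annotation
ELAC1	duck	detected	annotation
SMAD4	duck	detected	annotation
ME2	duck	detected	annotation
MAPK4	duck	detected	annotation
SKA1	duck	detected	annotation
CXXC1	duck	detected	annotation
MBD1	duck	detected	annotation
MYO5B	duck	detected	annotation
ACAA2	duck	detected	annotation
LIPG	duck	detected	annotation
C18orf32	duck	detected	annotation
RPL17	duck	detected	annotation
DYM	duck	detected	annotation
SMAD7	duck	detected	annotation
CTIF	duck	detected	annotation
NARS	ostrich	detected	annotation
FECH	ostrich	detected	annotation
ONECUT2	ostrich	detected	annotation
ST8SIA3	ostrich	detected	annotation
WDR7	ostrich	detected	annotation
TXNL1	ostrich	detected	annotation
TCF4	ostrich	detected	annotation
CCDC68	ostrich	detected	annotation
RAB27B	ostrich	detected	annotation
DYNAP	ostrich	detected	annotation
C18orf54	ostrich	detected	annotation
STARD6	ostrich	detected	annotation
POLI	ostrich	detected	annotation
MBD2	ostrich	detected	annotation
DCC	ostrich	detected	annotation
MEX3C	ostrich	detected	annotation
ELAC1	ostrich	detected	annotation
SMAD4	ostrich	detected	annotation
ME2	ostrich	detected	annotation
MAPK4	ostrich	detected	annotation
SKA1	ostrich	detected	annotation
CXXC1	ostrich	detected	annotation
MBD1	ostrich	detected	annotation
MYO5B	ostrich	detected	annotation
ACAA2	ostrich	detected	annotation
LIPG	ostrich	detected	annotation
C18orf32	ostrich	detected	annotation
RPL17	ostrich	detected	annotation
DYM	ostrich	detected	annotation
SMAD7	ostrich	detected	annotation
CTIF	ostrich	detected	annotation
NARS	chicken	detected	annotation
FECH	chicken	detected	annotation
ONECUT2	chicken	detected	annotation
ST8SIA3	chicken	detected	annotation
WDR7	chicken	detected	annotation
TXNL1	chicken	detected	annotation
TCF4	chicken	detected	annotation
CCDC68	chicken	not_detected	NA
RAB27B	chicken	not_detected	NA
DYNAP	chicken	detected	annotation
C18orf54	chicken	not_detected	NA
STARD6	chicken	not_detected	NA
POLI	chicken	not_detected	NA
MBD2	chicken	detected	annotation
DCC	chicken	not_detected	NA
MEX3C	chicken	not_detected	NA
ELAC1	chicken	not_detected	NA
SMAD4	chicken	detected	annotation
ME2	chicken	detected	annotation
MAPK4	chicken	not_detected	NA
SKA1	chicken	detected	annotation
CXXC1	chicken	not_detected	NA
MBD1	chicken	not_detected	NA
MYO5B	chicken	not_detected	NA
ACAA2	chicken	detected	annotation
LIPG	chicken	detected	annotation
C18orf32	chicken	detected	annotation
RPL17	chicken	detected	annotation
DYM	chicken	detected	annotation
SMAD7	chicken	detected	annotation
CTIF	chicken	detected	annotation
NARS	turkey	detected	annotation
FECH	turkey	detected	annotation
ONECUT2	turkey	detected	annotation
ST8SIA3	turkey	detected	annotation
WDR7	turkey	detected	annotation
TXNL1	turkey	detected	annotation
TCF4	turkey	detected	annotation
CCDC68	turkey	detected	annotation
RAB27B	turkey	not_detected	NA
DYNAP	turkey	detected	annotation
C18orf54	turkey	not_detected	NA
STARD6	turkey	not_detected	NA
POLI	turkey	not_detected	NA
MBD2	turkey	detected	annotation
DCC	turkey	not_detected	NA
MEX3C	turkey	not_detected	NA
ELAC1	turkey	not_detected	NA
SMAD4	turkey	detected	annotation
ME2	turkey	detected	annotation
MAPK4	turkey	not_detected	NA
SKA1	turkey	detected	annotation
CXXC1	turkey	not_detected	NA
MBD1	turkey	not_detected	NA
MYO5B	turkey	not_detected	NA
ACAA2	turkey	detected	annotation
LIPG	turkey	detected	annotation
C18orf32	turkey	detected	annotation
RPL17	turkey	detected	annotation
DYM	turkey	detected	annotation
SMAD7	turkey	detected	annotation
CTIF	turkey	detected	annotation
NARS	quail	detected	annotation
FECH	quail	detected	annotation
ONECUT2	quail	detected	annotation
ST8SIA3	quail	detected	annotation
WDR7	quail	detected	annotation
TXNL1	quail	detected	annotation
TCF4	quail	detected	annotation
CCDC68	quail	not_detected	NA
RAB27B	quail	not_detected	NA
DYNAP	quail	detected	reads
C18orf54	quail	not_detected	NA
STARD6	quail	not_detected	NA
POLI	quail	not_detected	NA
MBD2	quail	detected	reads
DCC	quail	not_detected	NA
MEX3C	quail	not_detected	NA
ELAC1	quail	not_detected	NA
SMAD4	quail	detected	reads
ME2	quail	detected	reads
MAPK4	quail	not_detected	NA
SKA1	quail	detected	reads
CXXC1	quail	not_detected	NA
MBD1	quail	not_detected	NA
MYO5B	quail	not_detected	NA
ACAA2	quail	detected	annotation
LIPG	quail	detected	annotation
C18orf32	quail	detected	annotation
RPL17	quail	detected	annotation
DYM	quail	detected	annotation
SMAD7	quail	detected	annotation
CTIF	quail	detected	annotation
NARS	guineafowl	detected	annotation
FECH	guineafowl	detected	annotation
ONECUT2	guineafowl	detected	annotation
ST8SIA3	guineafowl	detected	annotation
WDR7	guineafowl	detected	annotation
TXNL1	guineafowl	detected	annotation
TCF4	guineafowl	detected	annotation
CCDC68	guineafowl	not_detected	NA
RAB27B	guineafowl	not_detected	NA
DYNAP	guineafowl	detected	reads
C18orf54	guineafowl	not_detected	NA
STARD6	guineafowl	not_detected	NA
POLI	guineafowl	not_detected	NA
MBD2	guineafowl	detected	reads
DCC	guineafowl	not_detected	NA
MEX3C	guineafowl	not_detected	NA
ELAC1	guineafowl	not_detected	NA
SMAD4	guineafowl	detected	reads
ME2	guineafowl	detected	reads
MAPK4	guineafowl	not_detected	NA
SKA1	guineafowl	detected	reads
CXXC1	guineafowl	not_detected	NA
MBD1	guineafowl	not_detected	NA
MYO5B	guineafowl	detected	reads
ACAA2	guineafowl	detected	annotation
LIPG	guineafowl	detected	annotation
C18orf32	guineafowl	detected	annotation
RPL17	guineafowl	detected	annotation
DYM	guineafowl	detected	annotation
SMAD7	guineafowl	detected	annotation
CTIF	guineafowl	detected	annotation
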