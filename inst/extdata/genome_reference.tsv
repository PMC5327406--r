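gene	scaffold	start	end	strand
NARS	chr18	1	5000	+
FECH	chr18	10001	15000	+
ONECUT2	chr18	20001	25000	-
ST8SIA3	chr18	30001	35000	+
WDR7	chr18	40001	45000	+
TXNL1	chr18	50001	55000	-
TCF4	chr18	60001	65000	-
CCDC68	chr18	70001	75000	+
RAB27B	chr18	80001	85000	+
DYNAP	chr18	90001	95000	-
C18orf54	chr18	100001	105000	+
STARD6	chr18	110001	115000	+
POLI	chr18	120001	125000	+
MBD2	chr18	130001	135000	-
DCC	chr18	140001	145000	+
MEX3C	chr18	150001	155000	-
ELAC1	chr18	160001	165000	-
SMAD4	chr18	170001	175000	+
ME2	chr18	180001	185000	-
MAPK4	chr18	190001	195000	-
SKA1	chr18	200001	205000	+
CXXC1	chr18	210001	215000	+
MBD1	chr18	220001	225000	-
MYO5B	chr18	230001	235000	-
ACAA2	chr18	240001	245000	-
LIPG	chr18	250001	255000	-
C18orf32	chr18	260001	265000	+
RPL17	chr18	270001	275000	-
DYM	chr18	280001	285000	+
SMAD7	chr18	290001	295000	+
CTIF	chr18	300001	305000	+
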