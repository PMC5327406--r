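# Transcription note for the bundled fixtures

These tables are hand transcriptions of published comparative maps of the
avian DCC locus (gene orders of the human/duck reference and of chicken,
a genes-by-species detection matrix for the Galliformes, and a per-species
summary of where DCC itself was found). They are versioned with md5
checksums inside the package and exist to provide small worked examples;
they are not a re-annotation of any genome.

The reference order lists 31 genes: 7 upstream flank genes (NARS..TCF4),
the 17-gene segment disrupted in Galliformes and Passeriformes
(CCDC68..MYO5B) and 7 downstream flank genes (ACAA2..CTIF).

Editorial fill: the published text names 13 or 14 of the 17 segment genes
outright; the remaining positions (ELAC1, MAPK4, CXXC1, MBD1) were filled
from the human GRCh37 chr18 gene order. Only the segment's size (17
genes), not these names, enters any computed result.

Strand assignments and the coordinates (5 kb genes, 5 kb gaps) are
schematic; block structure, orientations and presence/absence calls are
the transcribed content.

In table1.tsv, 'paralog' means the best assembly hit was the Neogenin
paralog rather than DCC.
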