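order_name	species	assembly_top_hit	raw_reads	transcriptome
Galliformes	chicken	paralog	NO	NO
Galliformes	quail	paralog	NO	NO
Galliformes	turkey	paralog	NO	NO
Galliformes	guineafowl	paralog	NO	NO
Galliformes	brush turkey	none_available	YES	none_available
Anseriformes	duck	DCC	YES	YES
Columbiformes	rock pigeon	DCC	YES	YES
Cuculiformes	common cuckoo	DCC	YES	NO
Apodiformes	Anna's hummingbird	DCC	YES	none_available
Caprimulgiformes	chimney swift	DCC	YES	NO
Opisthocomiformes	hoazin	DCC	YES	YES
Chradriiformes	killdeer	DCC	YES	NO
Sphenisciformes	emperor penguin	DCC	YES	YES
Falconiformes	peregrine falcon	DCC	YES	YES
Psittaciformes	budgerigar	DCC	YES	NO
Passeriformes	rifleman	paralog	YES	none_available
Passeriformes	hooded crow	paralog	YES	YES
Passeriformes	ground tit	paralog	YES	YES
Passeriformes	ground finch	paralog	NO	none_available
Passeriformes	zebra finch	paralog	NO	NO
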