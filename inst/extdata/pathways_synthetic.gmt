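Protein biosynthesis	synthetic set: proteinogenic amino acids in the packaged library	HMDB0000172	HMDB0000687	HMDB0000883	HMDB0000167	HMDB0000161	HMDB0000148	HMDB0000641	HMDB0000191	HMDB0000158	HMDB0000159
Urea cycle	synthetic set: urea-cycle-linked metabolites in the packaged library	HMDB0000191	HMDB0000148	HMDB0000134
RNA transcription	synthetic set: ribonucleotides and nucleosides	HMDB0000045	HMDB0000538	HMDB0001273	HMDB0000288	HMDB0000296
Ammonia recycling	synthetic set: glutamine/glutamate/aspartate node	HMDB0000641	HMDB0000148	HMDB0000191
Purine metabolism	synthetic set: purine nucleotides and inosine	HMDB0000045	HMDB0000538	HMDB0001273	HMDB0000195	HMDB0000902
Glycolysis and energy	synthetic set: glycolytic and TCA intermediates	HMDB0000122	HMDB0000190	HMDB0000254	HMDB0000134
Choline metabolism	synthetic set: choline headgroup metabolites	HMDB0000097	HMDB0001565	HMDB0000086
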