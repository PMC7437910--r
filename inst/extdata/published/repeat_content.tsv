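family	cattle_bp	buffalo_bp
LINE	591242926	564818087
LTR	125345371	115039365
SINE	455612491	443033730
Simple repeat	20557705	16644633
Satellite	7090776	2966452
ncRNA	21196503	5714700
Others	55795102	53967410
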