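name,duration_mm_ss
Chauffeur,09:45
El Mourabbi,09:04
De Chinese Muur,09:50
One of the Boys,10:58
Samual,09:45
Turn it Around,09:26
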