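subset,prey_type,successes,trials
all,euptychiina,28,131
all,heliconius,23,131
all,spicauda,52,131
immature,euptychiina,19,90
immature,heliconius,20,90
immature,spicauda,30,90
adult,euptychiina,9,41
adult,heliconius,3,41
adult,spicauda,22,41
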