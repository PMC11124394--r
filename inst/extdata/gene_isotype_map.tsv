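gene	isotype
TUBB	βI
TUBB2A	βIIa
TUBB2B	βIIb
TUBB3	βIII
TUBB4	βIVa
TUBB2C	βIVb
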