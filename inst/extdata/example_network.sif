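TRIM28 activates PROM1
TRIM28 activates MYB
RELA activates PROM1
MYB activates E2F1
E2F1 activates E2F1
HIF1A activates PROM1 RELA
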