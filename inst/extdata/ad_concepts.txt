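# Alzheimer's-disease-related UMLS concept identifiers (bundled default
# whitelist; extend or replace with your own list).
C0002395
C0494463
C0276496
C0750900
C0750901
C1863051
C0011265
C0011269
C2931258
C0877784
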