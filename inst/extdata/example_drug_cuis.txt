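# Synthetic example list of clinical-drug concept identifiers.
# Real category lists are extracted from UMLS (drugs/chemicals) or iDISK
# (dietary supplements), which are licensed and not bundled.
C0000001
C0000002
C0000003
C0000004
C0000005
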