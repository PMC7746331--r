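rsid	reason
rs00003	associated with lipid traits
rs00009	associated with blood cell counts
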