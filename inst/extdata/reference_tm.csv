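model,rmsd,tm,role
CCCT3,2.0,332,training
CCCT5,3.4,321,training
CCCT7,5.0,311,training
CCCT6,4.1,316,validation
CCCTA2,2.1,329,validation
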