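LYSO_AUTOPHAGY_DEMO	synthetic demo stand-in for a curated lysosomal/autophagic list	Ctsb	Ctss	Ctsl	Lamp1	Lamp2	Sqstm1	Map1lc3b	Atg5	Atg7	Becn1	Gabarapl1	Tfeb
INFLAMMATION_DEMO	synthetic demo inflammatory-response set	Tnf	Il6	Il1b	Ccl2	Cxcl1	Nfkb1	Tlr4	Emr1
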