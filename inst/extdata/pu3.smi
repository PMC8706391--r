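# PU3, 9-butyl-8-(3,4,5-trimethoxybenzyl)-9H-purin-6-amine (literature structure of the Hsp90 inhibitor PU3)
PU3	CCCCn1c(Cc2cc(OC)c(OC)c(OC)c2)nc2c(N)ncnc21
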