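# Synthetic stand-in RBS library: four Shine-Dalgarno-bearing ribosome
# binding sites of the kind found on common cloning vectors (Ra-Rd), for
# use as the replaceable RBS part of TuPPE cassettes. Sequences are
# constructed examples, not measured parts. The native-RBS variant (Rn)
# has an empty sequence: the 500-bp promoter window already abuts the
# start codon, so the promoter donor's own RBS rides along.
name	sequence
Ra	AAGGAGGTTAATA
Rb	AAAGAGGAGAAAT
Rc	TCACACAGGAAAG
Rd	AGGAGGACAGCTA
Rn	
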