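# cel-let-7 mature arms (miRBase v22.1); guide = arm with most reported reads
name	seq5p	seq3p	guide_arm
cel-let-7	UGAGGUAGUAGGUUGUAUAGUU	CUAUGCAAUUUUCUACCUUACC	5p
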