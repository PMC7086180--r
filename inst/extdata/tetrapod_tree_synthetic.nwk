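((rat:0.05,chicken:0.05)amniote:0.05,frog:0.10)tetrapod;
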