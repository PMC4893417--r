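0.818942873462
0.497681568553
-0.731642978371
-0.625203002340
-0.461880708840
0.807499129156
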