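# Demonstration accident chains (arrow-delimited causal-factor codes).
# Chain 1: unfamiliar road -> improper overtaking -> collision -> leakage
# Chain 2: fatigue driving -> collision -> tank damaged -> explosion
H10→H05→A01→A06
H01→A01→V04→A07
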