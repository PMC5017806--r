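# NO channel as commonly printed; element-unbalanced (N, O) -- validation fixture
1 Fe2+ + 2 NO + 1 H+ -> 1 Fe3+ + 1 HNO # eq6
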