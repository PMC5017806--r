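# NDFO reaction network, corrected NO channel (element-balanced 1:1 form)
2 Fe2+ + 1 NO3- + 2 H+ -> 2 Fe3+ + 1 NO2- + 1 H2O # eq1
5 Fe2+ + 1 NO3- + 6 H+ -> 5 Fe3+ + 1/2 N2 + 3 H2O # eq2
1 NO2- + 1 H+ -> 1 HNO2 # eq3
2 HNO2 -> 1 NO2 + 1 NO + 1 H2O # eq4
2 Fe2+ + 1 NO2 + 2 H+ -> 2 Fe3+ + 1 NO + 1 H2O # eq5
1 Fe2+ + 1 NO + 1 H+ -> 1 Fe3+ + 1 HNO # eq6
2 HNO -> 1 N2O + 1 H2O # eq7
2 NO + 1 O2 -> 2 NO2 # eq8
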