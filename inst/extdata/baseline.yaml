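# Baseline pharmaceutical-market scenario: non-R&D production cost 13 and
# revenue 22; R&D cost 18 and revenue 35. Success rates, tax-incentive rate,
# group size and selection intensity as in the weak-selection, high-incentive
# setting.
Cpl: 13
Cph: 18
RT: 22
RI: 35
eta1: 0.8
eta2: 0.4
lam: 0.3
"N": 6
xi: 0.1
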