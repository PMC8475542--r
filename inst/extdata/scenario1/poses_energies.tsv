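c0.e0	-1561.3761
c1.e0	-1549.2820
c2.e0	-1491.4554
c3.e0	-1466.9290
c4.e0	-1346.3149
c5.e0	-1498.4721
c6.e0	-1523.5795
c7.e0	-1553.1272
c8.e0	-1492.1571
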