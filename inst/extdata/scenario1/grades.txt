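# pos aa grade
1 A 2
2 A 2
3 A 2
4 A 2
5 A 2
6 A 2
7 A 2
8 A 2
9 A 2
10 A 2
11 A 2
12 A 2
13 A 8
14 A 8
15 A 2
16 A 2
17 A 2
18 A 2
19 A 2
20 A 2
21 A 2
22 A 2
23 A 8
24 A 8
25 A 8
26 A 8
27 A 8
28 A 2
29 A 2
30 A 2
31 A 2
32 A 2
33 A 2
34 A 2
35 A 2
36 A 8
37 A 8
38 A 8
39 A 2
40 A 2
41 A 2
42 A 2
43 A 2
44 A 2
45 A 2
46 A 2
47 A 8
48 A 8
49 A 2
50 A 2
51 A 2
52 A 2
53 A 2
54 A 2
55 A 2
56 A 2
57 A 2
58 A 2
59 A 2
60 A 2
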