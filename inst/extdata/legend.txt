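1 Af 0 0 255
2 Am 0 120 255
3 Aw 70 170 250
4 BWh 255 0 0
5 BWk 255 150 150
6 BSh 245 165 0
7 BSk 255 220 100
8 Csa 255 255 0
9 Csb 200 200 0
10 Csc 150 150 0
11 Cwa 150 255 150
12 Cwb 100 200 100
13 Cwc 50 150 50
14 Cfa 200 255 80
15 Cfb 100 255 80
16 Cfc 50 200 0
17 Dsa 255 0 255
18 Dsb 200 0 200
19 Dsc 150 50 150
20 Dsd 150 100 150
21 Dwa 170 175 255
22 Dwb 90 120 220
23 Dwc 75 80 180
24 Dwd 50 0 135
25 Dfa 0 255 255
26 Dfb 55 200 255
27 Dfc 0 125 125
28 Dfd 0 70 95
29 ET 178 178 178
30 EF 102 102 102
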