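lon,lat,clade
12.35,44.12,1
12.41,44.09,1
13.02,43.88,1
14.55,42.71,1
15.10,42.40,1
16.33,41.95,1
17.08,41.12,1
18.20,40.45,1
19.75,40.02,1
21.40,39.55,1
22.90,38.90,2
23.15,38.72,2
23.80,38.30,2
24.60,37.95,2
25.20,37.60,2
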