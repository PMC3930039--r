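site_id,region,n_zz,n_ez,n_ee
1,Midwest,48,0,0
2,Midwest,24,0,0
3,Midwest,48,0,0
4,Midwest,48,0,0
5,Midwest,24,0,0
6,EastCoast,21,2,1
7,EastCoast,18,13,0
8,EastCoast,60,17,11
9,EastCoast,37,6,5
10,EastCoast,17,5,2
11,EastCoast,42,6,0
12,EastCoast,5,2,3
13,EastCoast,16,1,0
14,EastCoast,18,2,0
15,EastCoast,9,2,0
16,EastCoast,10,0,0
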