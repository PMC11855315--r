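pore,area_um2_automated,perimeter_um_automated,orientation_deg_automated,area_um2_imagej,perimeter_um_imagej,orientation_deg_imagej
1,1000,151,51,1271,192,78
2,1262,139,124,1269,134,137
3,1119,137,108,1123,137,129
4,1238,191,170,1096,166,140
5,487,88,121,442,84,129
6,866,179,163,876,178,163
7,4730,421,111,4772,393,120
8,2710,275,96,2696,259,80
9,4942,362,101,5228,312,100
10,2613,250,115,2551,242,125
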