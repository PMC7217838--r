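locus,allele,ad_count,ad_total,gp_count,gp_total
A,A*02:01,11,108,224,2150
A,A*02:03,11,108,131,2150
A,A*02:06,0,108,67,2150
A,A*02:07,14,108,185,2150
A,A*11:01,31,108,542,2150
A,A*11:02,6,108,86,2150
A,A*24:02,16,108,368,2150
A,A*26:01,2,108,63,2150
A,A*29:01,1,108,3,2150
A,A*30:01,3,108,48,2150
A,A*31:01,1,108,58,2150
A,A*32:01,1,108,15,2150
A,A*33:03,9,108,279,2150
A,A*34:01,1,108,1,2150
A,A*68:01,1,108,3,2150
B,B*07:05,2,108,1,2180
B,B*08:01,2,108,5,2180
B,B*13:01,6,108,122,2180
B,B*13:02,2,108,51,2180
B,B*15:01,4,108,83,2180
B,B*15:02,1,108,80,2180
B,B*15:07,1,108,1,2180
B,B*15:11,1,108,23,2180
B,B*15:18,1,108,14,2180
B,B*15:25,1,108,18,2180
B,B*27:04,1,108,57,2180
B,B*35:01,6,108,66,2180
B,B*38:02,11,108,97,2180
B,B*39:01,3,108,47,2180
B,B*40:01,23,108,410,2180
B,B*40:02,5,108,57,2180
B,B*40:06,2,108,38,2180
B,B*44:02,1,108,10,2180
B,B*46:01,11,108,235,2180
B,B*48:01,3,108,22,2180
B,B*51:01,2,108,97,2180
B,B*52:01,1,108,30,2180
B,B*54:01,2,108,72,2180
B,B*55:02,2,108,58,2180
B,B*56:03,2,108,7,2180
B,B*58:01,11,108,262,2180
B,B*67:01,1,108,8,2180
C,C*01:02,20,108,354,2178
C,C*03:02,12,108,263,2178
C,C*03:03,10,108,126,2178
C,C*03:04,11,108,242,2178
C,C*04:01,1,108,93,2178
C,C*04:03,2,108,38,2178
C,C*05:01,1,108,8,2178
C,C*06:02,2,108,72,2178
C,C*07:02,36,108,423,2178
C,C*08:01,4,108,150,2178
C,C*12:02,3,108,88,2178
C,C*14:02,2,108,79,2178
C,C*15:02,3,108,107,2178
C,C*15:05,1,108,1,2178
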