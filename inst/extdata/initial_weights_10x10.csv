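-1.0,1.0,1.0,1.0,-1.0,1.0,-1.0,1.0,-1.0,1.0
1.0,-1.0,1.0,1.0,1.0,-1.0,1.0,1.0,-1.0,1.0
1.0,-1.0,-0.4,-1.0,-0.8,-1.0,-1.0,1.0,-1.0,-1.0
-1.0,-1.0,-1.0,-1.0,-1.0,-1.0,-1.0,-1.0,1.0,1.0
-1.0,-1.0,0.2,-1.0,-1.0,-1.0,1.0,-1.0,1.0,1.0
-1.0,1.0,0.5,1.0,1.0,1.0,-1.0,1.0,-1.0,0.7
1.0,-0.5,-0.6,0.7,1.0,1.0,-0.7,1.0,1.0,-1.0
-1.0,1.0,1.0,-0.9,-1.0,-1.0,1.0,-1.0,1.0,1.0
1.0,-1.0,1.0,1.0,-1.0,-1.0,1.0,-1.0,1.0,-1.0
0.3,1.0,-1.0,-1.0,-0.2,-1.0,0.1,-1.0,1.0,-1.0
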