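sample,mean_firing_rate_hz,predicted_qsar_hz
L-Glu:L-Asp,535.4877,536.0542
L-Glu:L-Asp:L-Phe,436.2721,492.8753
L-Lys:L-Phe:L-Glu,542.9443,563.6253
L-Glu:L-Phe:L-His,567.0562,521.7084
L-Glu:L-Phe:PLLA,498.2888,551.9483
L-Lys:L-Phe:L-His:PLLA,650.4798,-901.3635
L-Glu:L-Arg,732.9516,-2041.8
L-Asp,529.072,723.4966
L-Phe:L-Lys,768.2345,-2619.1
L-Glu:L-Asp:L-Pro,617.3223,1345.4
L-Phe,491.5065,471.338
L-Glu:L-Phe,665.2995,-1084.7
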