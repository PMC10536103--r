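proteinoid,n_spikes,mean_isi_s,frequency_mhz
L-Glu:L-Asp,726,22.24,44.97
L-Glu:L-Asp:L-Phe,359,50.48,19.80
L-Lys:L-Phe:L-Glu,210,85.75,11.66
L-Glu:L-Phe:L-His,382,42.21,23.69
L-Glu:L-Phe:PLLA,555,32.71,30.57
L-Lys:L-Phe:L-His:PLLA,195,77.29,12.94
L-Glu:L-Arg,29,544.68,48.28
L-Asp,779,20.71,36.26
L-Phe:L-Lys,28,666.11,1.50
L-Glu:L-Asp:L-Pro,8,2541.00,0.39
L-Phe,900,12.32,81.15
L-Glu:L-Phe,12,1412.55,0.71
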