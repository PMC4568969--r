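>SYN_NRF2 NRF2_like_synthetic
A [ 17  1  1  1  1 17 17  1  1  1 ]
C [  1 17 17  1  1  1  1  1  1  1 ]
G [  1  1  1 17 17  1  1 17  1 17 ]
T [  1  1  1  1  1  1  1  1 17  1 ]
>SYN_FLAT uniform_synthetic
1 1 1 1 1 1
1 1 1 1 1 1
1 1 1 1 1 1
1 1 1 1 1 1
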