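>MA0006.1 Ahr::Arnt
A  [ 3 0 0 0 0 0 ]
C  [ 8 0 23 0 0 0 ]
G  [ 2 23 0 23 0 23 ]
T  [ 11 1 1 1 24 1 ]
>SYNT0001.1 Ebox-bHLH-synthetic
A  [ 85 85 5 5 85 5 5 5 5 5 5 85 ]
C  [ 5 5 85 85 5 85 5 5 5 5 85 5 ]
G  [ 5 5 5 5 5 5 85 5 85 85 5 5 ]
T  [ 5 5 5 5 5 5 5 85 5 5 5 5 ]
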