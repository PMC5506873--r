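cluster	position
FS2	12
FS2	17
FS2	22
FS2	27
FS4C	40
FS4C	45
FS4C	50
FS4C	55
FS4B	70
FS4B	75
FS4B	80
FS4B	85
FS4A	100
FS4A	105
FS4A	110
FS4A	115
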