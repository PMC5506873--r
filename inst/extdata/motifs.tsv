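name	pattern
L1	TSCCPxW
L2	MPCxxKxxE
L3	ExMxCxxGCxxG
P1B	TSCCCPxW
NIFE_CXXC	CxxC
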