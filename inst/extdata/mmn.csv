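label,r_t,m_t,r_c,m_c
Azulay,0,5,0,5
Berg,3,3,0,6
Leger,4,3,2,5
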