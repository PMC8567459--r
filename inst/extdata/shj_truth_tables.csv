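# Category-A membership for the six classic three-binary-dimension category
# structures (types III and V transcribed from the published figure; the
# others follow their standard definitions: I = first bit, II = exclusive-or
# of bits 1-2, IV = majority, VI = parity).
# Columns: type, b1, b2, b3 give the bit patterns belonging to category A.
type,b1,b2,b3
I,0,0,0
I,0,0,1
I,0,1,0
I,0,1,1
II,0,0,0
II,0,0,1
II,1,1,0
II,1,1,1
III,0,0,0
III,0,0,1
III,0,1,0
III,1,0,1
IV,0,0,0
IV,0,0,1
IV,0,1,0
IV,1,0,0
V,0,0,0
V,0,0,1
V,0,1,0
V,1,1,1
VI,0,0,0
VI,0,1,1
VI,1,0,1
VI,1,1,0
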