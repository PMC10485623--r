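# Three-species worked example:
#   A(t+1) = B(t) and C(t)
#   B(t+1) = C(t)
#   C(t+1) = A(t) or B(t)
SPECIES A gene
SPECIES B gene
SPECIES C gene
RULE A <- ACT( (B & C) ) INH( )
RULE B <- ACT( C ) INH( )
RULE C <- ACT( A ; B ) INH( )
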