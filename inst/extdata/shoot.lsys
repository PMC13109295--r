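# Stochastic branching shoot with leaves at branch points and tips; leaf
# count varies between derivations. Perspective or oblique cameras suit it.
angle: 25
step: 1
axiom: !(0.12) F(0.8) A(4)
A(n) : n > 0 -> (0.5) F(0.9) [ +(32) A(n - 1) ] [ -(30) A(n - 1) ] | (0.3) F(0.9) [ +(24) A(n - 1) ] [ -(55) L ] | (0.2) F(0.7) [ &(40) L ] A(n - 1)
A(n) : n <= 0 -> [ &(35) L ]
sub L = leaf.lsys @ 6 class=leaf
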