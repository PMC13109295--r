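# Deterministic flat rosette: 8 equal leaves on short pitched petioles,
# azimuthally distributed by rolls of the golden angle about the vertical
# axis. Intended for top-down orthographic imaging.
angle: 45
step: 0.4
axiom: !(0.06) R(8, 137.5)
R(n, a) : n > 0 -> [ /(a * n) &(62) F(0.35) L ] R(n - 1, a)
R(n, a) : n <= 0 ->
sub L = leaf.lsys @ 6 class=leaf
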