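# Ovate leaf blade: a closed polygon traced in the turtle's H-L plane.
# Two opposite-bowing arcs (A: left margin, B: right margin) meet at the
# tip; '}' fan-triangulates the captured outline. All distances and angles
# are explicit so the blade is independent of the enclosing plant
# grammar's defaults.
angle: 16
step: 0.45
axiom: { . -(40) A(5) +(116) B(5) }
A(n) : n > 0 -> f(0.45) . +(16) A(n - 1)
A(n) : n <= 0 ->
B(n) : n > 0 -> f(0.45) . +(16) B(n - 1)
B(n) : n <= 0 ->
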