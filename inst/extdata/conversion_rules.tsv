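# Linear unit-conversion rules: value_in_to = value_in_from * factor.
# One edge per row; inverses and chains are derived transitively.
from	to	factor
m	cm	100
m	mm	1000
kg	g	1000
g	mg	1000
L	mL	1000
L	dL	10
day	h	24
h	min	60
min	s	60
week	day	7
month	day	30.44
year	day	365.25
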