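format-version: 1.2
! Compact measurement-unit vocabulary in the style of the Units of
! Measurement Ontology (UO): formal name, synonyms/symbols, is_a grouping.
! Curated subset covering common clinical phenotype units.

[Term]
id: HU:0000001
name: length unit

[Term]
id: HU:0000002
name: mass unit

[Term]
id: HU:0000003
name: time unit

[Term]
id: HU:0000004
name: volume unit

[Term]
id: HU:0000005
name: pressure unit

[Term]
id: HU:0000011
name: meter
synonym: "m" EXACT []
synonym: "metre" EXACT []
synonym: "meters" EXACT []
is_a: HU:0000001 ! length unit

[Term]
id: HU:0000012
name: centimeter
synonym: "cm" EXACT []
synonym: "centimetre" EXACT []
synonym: "centimeters" EXACT []
is_a: HU:0000001 ! length unit

[Term]
id: HU:0000013
name: millimeter
synonym: "mm" EXACT []
synonym: "millimetre" EXACT []
is_a: HU:0000001 ! length unit

[Term]
id: HU:0000021
name: kilogram
synonym: "kg" EXACT []
synonym: "kilograms" EXACT []
is_a: HU:0000002 ! mass unit

[Term]
id: HU:0000022
name: gram
synonym: "g" EXACT []
synonym: "grams" EXACT []
synonym: "gramme" EXACT []
is_a: HU:0000002 ! mass unit

[Term]
id: HU:0000023
name: milligram
synonym: "mg" EXACT []
synonym: "milligrams" EXACT []
is_a: HU:0000002 ! mass unit

[Term]
id: HU:0000031
name: liter
synonym: "L" EXACT []
synonym: "litre" EXACT []
is_a: HU:0000004 ! volume unit

[Term]
id: HU:0000032
name: milliliter
synonym: "mL" EXACT []
synonym: "millilitre" EXACT []
is_a: HU:0000004 ! volume unit

[Term]
id: HU:0000033
name: deciliter
synonym: "dL" EXACT []
synonym: "decilitre" EXACT []
is_a: HU:0000004 ! volume unit

[Term]
id: HU:0000041
name: millimeter of mercury
synonym: "mmHg" EXACT []
is_a: HU:0000005 ! pressure unit

[Term]
id: HU:0000051
name: second
synonym: "s" EXACT []
synonym: "seconds" EXACT []
is_a: HU:0000003 ! time unit

[Term]
id: HU:0000052
name: minute
synonym: "min" EXACT []
synonym: "minutes" EXACT []
is_a: HU:0000003 ! time unit

[Term]
id: HU:0000053
name: hour
synonym: "h" EXACT []
synonym: "hours" EXACT []
is_a: HU:0000003 ! time unit

[Term]
id: HU:0000054
name: day
synonym: "days" EXACT []
is_a: HU:0000003 ! time unit

[Term]
id: HU:0000055
name: week
synonym: "weeks" EXACT []
is_a: HU:0000003 ! time unit

[Term]
id: HU:0000056
name: month
synonym: "months" EXACT []
is_a: HU:0000003 ! time unit

[Term]
id: HU:0000057
name: year
synonym: "years" EXACT []
is_a: HU:0000003 ! time unit
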