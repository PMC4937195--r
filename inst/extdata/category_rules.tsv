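# Hard category-matching rules, applied before frequency and lexical
# matching. Patterns are case-insensitive regular expressions matched
# against whole category labels. An empty target_pattern maps the source
# category to null (missing). Higher priority wins; the table is fully
# user-overridable.
source_pattern	target_pattern	priority
^never$	^(never|no)$	10
^no$	^(no|never)$	10
^ever$	^(ever|yes)$	10
^yes$	^(yes|ever)$	10
^(missing|unknown|not specified|don'?t know|no answer)$		5
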