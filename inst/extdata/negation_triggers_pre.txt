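# Pre-mention negation triggers (NegEx-style), one phrase per line.
no
not
without
denies
denied
deny
no evidence of
no sign of
no signs of
negative for
free of
absence of
absent
rules out
ruled out
cannot see
never had
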