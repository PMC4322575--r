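# Post-mention negation triggers, one phrase per line.
was ruled out
is ruled out
were ruled out
ruled out
unlikely
not present
was negative
is negative
not demonstrated
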