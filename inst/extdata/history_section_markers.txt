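# Section markers opening a patient-history section.
past medical history
medical history
past surgical history
history of present illness
social history
pmh
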