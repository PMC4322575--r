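# Other section markers; these close a history/family-history section.
physical exam
physical examination
review of systems
assessment
plan
impression
medications
allergies
labs
chief complaint
hospital course
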