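# survival outcome: predators affect survival but are unobserved;
# they have no path into rice, so they can be ignored for the total effect
drought -> rice
drought -> survival
rice -> survival
predators -> survival
unobserved: predators
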