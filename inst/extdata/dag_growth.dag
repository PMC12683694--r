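# hypothesized causal structure for the landscape effect on growth:
# drought is a common cause of rice cover and growth
drought -> rice
drought -> growth
rice -> growth
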