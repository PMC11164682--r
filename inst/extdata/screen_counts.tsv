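metric	value
animals_dissected	84
animals_with_lesions	62
lesions_isolated	127
lesions_sequenced	110
integration_sites	2058
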