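chr21	40	220	APP
chr21	450	560	SOD1
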