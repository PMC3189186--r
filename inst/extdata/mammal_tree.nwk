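((((((human,chimp),macaque),((mouse,rat),(guinea_pig,rabbit))),((cow,horse),(dog,cat))),opossum),platypus);
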