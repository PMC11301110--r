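# message-level negation cues; one term per line (clitic n't produced by the tokenizer)
not
no
never
n't
none
nobody
nothing
without
hardly
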