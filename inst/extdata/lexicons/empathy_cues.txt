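# empathy cue phrases, matched case-insensitively over the token stream
i can relate
i feel the same
i know how you feel
sending hugs
be strong
thinking of you
thinking of you all
i am with you
i 'm with you
you are not alone
we are with you
hang in there
my heart goes out to you
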