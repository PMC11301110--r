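# intensity boosters (degree adverbs that raise valence), after the VADER booster list
# multiword entries are matched as token n-grams
absolutely
amazingly
awfully
completely
considerably
decidedly
deeply
enormously
entirely
especially
exceptionally
extremely
fabulously
greatly
highly
hugely
incredibly
intensely
majorly
particularly
purely
quite
really
remarkably
so much
substantially
thoroughly
totally
tremendously
truly
unbelievably
unusually
utterly
very
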