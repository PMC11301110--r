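# Synthetic stand-in category dictionary for the 3-of-5 cohesion baseline.
# NOT the proprietary LIWC dictionary: small open word lists compiled for
# this package, in the same wildcard format (trailing * = prefix match).
%CAT we
we
us
our
ours
ourselves
lets
let's
we'd
we'll
we're
we've
%CAT positive_emotion
love*
good
great*
happ*
hope*
glad
nice*
support*
thank*
wonderful*
amazing*
comfort*
warm*
care*
caring
kind*
encourag*
appreciat*
joy*
beautiful*
positiv*
strong
better
best
fond
help*
%CAT family
famil*
husband*
wife
wives
mother*
mom*
father*
dad*
sister*
brother*
son
sons
daughter*
kid
kids
child*
parent*
grandm*
grandp*
aunt*
uncle*
cousin*
%CAT friend
friend*
buddy
buddies
pal
pals
companion*
neighbor*
neighbour*
roommate*
mate
mates
bestie*
%CAT affiliation
group*
together
member*
belong*
team*
communit*
circle*
club*
join*
ally
allies
social*
share
shared
sharing
connect*
everyone
peer
peers
we
us
our
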