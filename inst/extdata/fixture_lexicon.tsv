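# sentitrace packaged fixture valence lexicon
# term <TAB> valence in [-4, 4]; sections [boosters] (term <TAB> increment)
# and [negators] (one term per line) follow.
good	1.9
great	3.1
awesome	3.1
excellent	2.7
love	3.2
loved	2.9
like	1.5
liked	1.6
support	1.7
supportive	2.0
helpful	1.8
helps	1.4
hope	1.9
hopeful	2.3
safe	1.8
safer	1.9
trust	2.3
trusted	2.1
trustworthy	2.4
reassuring	1.9
reassured	1.9
effective	2.1
useful	1.9
benefit	1.9
benefits	1.9
brilliant	2.8
fantastic	2.6
amazing	2.8
happy	2.7
glad	2.0
relief	1.6
relieved	2.0
protect	1.3
protects	1.3
protected	1.5
win	2.8
success	2.7
successful	2.7
easy	1.9
simple	1.1
smooth	1.5
works	1.4
working	1.1
free	2.3
fair	2.1
clear	1.2
calm	1.3
confident	2.2
convenient	1.7
praise	2.4
praised	2.3
thank	1.9
thanks	1.9
grateful	2.4
welcome	2.0
positive	2.3
improvement	2.1
improved	2.0
improves	1.9
better	1.9
best	3.2
perfect	2.7
nice	1.8
wonderful	2.7
superb	3.0
encouraging	2.1
encouraged	1.9
recommend	1.6
recommended	1.7
reliable	2.0
robust	1.6
innovative	1.9
smart	1.7
proud	2.1
delighted	2.9
impressive	2.3
impressed	2.2
keen	1.4
enthusiastic	2.3
optimism	2.4
optimistic	2.4
comfort	1.9
comfortable	1.9
pleasant	2.2
pleased	2.2
promising	1.9
progress	1.7
genius	2.9
valuable	2.1
worth	1.3
worthwhile	2.1
favourite	2.0
favorite	2.0
enjoy	2.2
enjoyed	2.3
excited	2.4
exciting	2.4
thrilled	2.9
fine	0.8
okay	0.9
ok	0.8
agree	1.5
agreed	1.4
approve	1.8
approved	1.9
victory	2.9
celebrate	2.7
celebrated	2.6
brave	2.2
kind	2.4
generous	2.3
honest	2.3
transparent	1.6
secure	1.7
bad	-2.5
terrible	-2.1
awful	-2.0
horrible	-2.5
worst	-3.1
worse	-2.1
hate	-2.7
hated	-2.7
fear	-2.2
fears	-2.1
afraid	-2.2
scared	-2.2
scary	-2.2
worry	-1.9
worried	-1.9
worries	-1.9
worrying	-1.9
concern	-1.2
concerned	-1.4
concerns	-1.2
risk	-1.1
risks	-1.1
risky	-1.6
danger	-2.4
dangerous	-2.4
fail	-2.3
failed	-2.3
failure	-2.6
broken	-1.9
breach	-2.0
breached	-2.0
leak	-1.6
leaked	-1.7
intrusive	-1.9
invasive	-1.8
creepy	-1.7
distrust	-2.1
mistrust	-2.0
suspicious	-1.5
sceptical	-1.2
skeptical	-1.2
doubt	-1.4
doubtful	-1.5
useless	-1.9
pointless	-1.8
waste	-1.8
wasted	-1.9
flaw	-1.6
flawed	-1.8
buggy	-1.7
glitch	-1.3
crash	-1.7
crashed	-1.8
slow	-1.2
confusing	-1.5
confused	-1.4
chaos	-2.2
chaotic	-2.1
shambles	-2.3
disaster	-3.1
disastrous	-3.0
angry	-2.3
anger	-2.2
furious	-2.7
outrage	-2.5
outrageous	-2.4
annoyed	-1.6
annoying	-1.7
frustrated	-2.0
frustrating	-2.1
disappointed	-2.0
disappointing	-2.1
sad	-2.1
upset	-1.9
unhappy	-1.8
problem	-1.5
problems	-1.5
issue	-0.8
issues	-0.9
error	-1.6
errors	-1.7
wrong	-1.7
lie	-2.1
lies	-2.1
lying	-2.2
dishonest	-2.2
corrupt	-2.6
scam	-2.6
fraud	-2.8
spy	-1.6
spying	-1.8
snooping	-1.7
orwellian	-2.3
authoritarian	-2.0
invasion	-2.1
violate	-2.3
violation	-2.4
abuse	-2.8
misuse	-1.9
threat	-1.8
threats	-1.9
harm	-2.1
harmful	-2.3
panic	-2.2
crisis	-1.9
death	-2.9
deaths	-2.9
die	-2.9
dying	-2.9
sick	-1.5
illness	-1.6
infection	-1.4
infected	-1.6
outbreak	-1.4
refuse	-1.2
refused	-1.3
reject	-1.4
rejected	-1.6
oppose	-1.3
opposed	-1.3
insecure	-1.8
unsafe	-1.9
unreliable	-1.8
nightmare	-2.6
dreadful	-2.4
pathetic	-2.2
ridiculous	-1.6
stupid	-2.2
idiotic	-2.3
nonsense	-1.7
[boosters]
very	0.293
really	0.3
extremely	0.4
absolutely	0.35
incredibly	0.4
so	0.25
totally	0.3
utterly	0.4
deeply	0.3
hugely	0.35
particularly	0.25
especially	0.3
quite	0.2
fairly	0.15
rather	0.15
slightly	-0.2
somewhat	-0.15
marginally	-0.2
[negators]
not
no
never
none
neither
nor
cannot
can't
won't
don't
doesn't
didn't
isn't
aren't
wasn't
weren't
shouldn't
couldn't
wouldn't
ain't
without
lack
lacking
hardly
scarcely
rarely
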