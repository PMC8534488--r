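# Bundled mini sentiment lexicon (token, valence): the synthetic
# emotion-lexicon words plus a few generic valenced words. Small and
# versioned so polarity unit tests are exact.
token	valence
furious	-2.2
outraged	-2.4
rage	-2.6
angry	-2.0
infuriating	-2.3
livid	-2.5
afraid	-1.9
terrified	-2.7
scared	-2.0
frightening	-2.2
panic	-2.1
dread	-2.3
heartbroken	-2.4
grieving	-2.2
mourning	-2.0
sorrow	-2.1
devastated	-2.5
tearful	-1.8
delighted	2.3
thrilled	2.5
wonderful	2.4
fantastic	2.6
joyful	2.2
celebrating	2.0
hopeful	1.9
optimistic	2.1
promising	1.8
reassuring	1.7
encouraged	2.0
uplifting	1.9
good	2.0
great	2.4
happy	2.1
love	2.3
safe	1.5
effective	1.6
bad	-2.0
terrible	-2.4
awful	-2.3
dangerous	-1.8
toxic	-2.1
worried	-1.6
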