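# Published tweet counts by topic and by emotion for a 60-day COVID-19
# vaccine discussion corpus (2020-12-16 to 2021-02-13; 7,948,886 tweets
# after deduplication). Shipped so per-category percentage shares and
# polarity aggregates can be recomputed arithmetically from the counts.
# The printed per-category count for hopefulness duplicates the sadness
# count in the source table; the positive-polarity aggregate allows the
# hopefulness count to be derived as positive - joy.
group	key	count
total	corpus	7948886
topic	topic01	690357
topic	topic02	658115
topic	topic03	593425
topic	topic04	540065
topic	topic05	292217
topic	topic06	250337
topic	topic07	243934
topic	topic08	232780
topic	topic09	202164
topic	topic10	198967
topic	topic11	194578
topic	topic12	189468
emotion	fear	3002467
emotion	sadness	406095
emotion	anger	312398
emotion	neutral	1582221
emotion	joy	1751729
aggregate	negative	3720960
aggregate	positive	2645705
aggregate	neutral	1582221
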