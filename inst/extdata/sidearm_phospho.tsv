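species	bead_index
NfM	120
NfM	152
NfM	183
NfM	215
NfM	247
NfM	278
NfM	310
NfM	342
NfM	373
NfM	405
NfM	437
NfM	468
NfM	500
NfH	180
NfH	190
NfH	200
NfH	209
NfH	219
NfH	229
NfH	239
NfH	248
NfH	258
NfH	268
NfH	278
NfH	287
NfH	297
NfH	307
NfH	317
NfH	327
NfH	336
NfH	346
NfH	356
NfH	366
NfH	375
NfH	385
NfH	395
NfH	405
NfH	414
NfH	424
NfH	434
NfH	444
NfH	453
NfH	463
NfH	473
NfH	483
NfH	493
NfH	502
NfH	512
NfH	522
NfH	532
NfH	541
NfH	551
NfH	561
NfH	571
NfH	580
NfH	590
NfH	600
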