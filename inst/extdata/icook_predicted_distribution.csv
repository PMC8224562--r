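category,count
Chinese,1264
Japanese,961
Korean,1272
Thai,584
American,315
Italian,571
French,382
Spanish,264
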