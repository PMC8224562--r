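category,before,after,reported_rate
Chinese,1321,1211,91.6
Japanese,1231,1096,89.0
Korean,1333,1212,90.9
Thai,1021,920,90.1
American,670,562,83.8
Italian,1836,1623,88.3
French,949,713,75.1
Spanish,821,637,77.5
unknown,6121,5349,87.3
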