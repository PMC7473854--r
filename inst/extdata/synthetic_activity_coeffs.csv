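"feature","position","weight"
"G",1,0.01134
"A",3,-0.01332
"A",4,0.08907
"T",5,0.02981
"C",7,0.01312
"T",9,0.07666
"T",10,0.01007
"G",14,-0.06035
"C",15,0.01575
"A",17,-0.07016
"C",18,0.0385
"T",20,0.04524
"C",24,0.07978
"G",25,-0.05202
"G",26,-0.02282
"C",27,-0.01339
"C",28,0.03791
"T",31,-0.09472
"T",32,0.02341
"T",34,0.00635
"CC",2,-0.04262
"CC",3,-0.04585
"TC",4,-0.0238
"AT",5,-0.04462
"AA",6,-0.01114
"AC",7,-0.00247
"GA",13,-0.05481
"TC",14,0.01167
"AT",17,0.03678
"CG",18,0.05461
"AT",19,-0.03228
"AA",20,0.03331
"TT",21,0.04088
"TA",22,-0.028
"AT",23,0.03931
"GG",24,-0.05654
"GC",25,-0.08076
"AC",26,-0.06072
"TG",27,0.03084
"AA",28,0.00215
"TA",29,-0.00719
"TC",30,-0.00725
"CG",31,-0.00193
"AT",33,-0.03222
"TT",34,0.01925
"intercept",,0.45
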