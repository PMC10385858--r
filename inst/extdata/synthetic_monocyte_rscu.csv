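codon,monocyte_like
AAA,1.0769091074185053
AAC,0.91905865573185952
AAG,0.92309089258149457
AAT,1.0809413442681406
ACA,1.0687488781188297
ACC,0.94991922455573508
ACG,0.92766110213606179
ACT,1.0536707951893736
AGA,1.0962923446252333
AGC,0.95010615711252666
AGG,0.91864497199253137
AGT,1.0302547770700636
ATA,0.80150214592274682
ATC,1.389216738197425
ATT,0.80928111587982832
CAA,1.0562685093780848
CAC,0.92795914645267186
CAG,0.94373149062191508
CAT,1.072040853547328
CCA,1.0693929249977381
CCC,0.91920745498959555
CCG,0.94779697819596487
CCT,1.0636026418167013
CGA,1.0717524673246199
CGC,0.91971192317951456
CGG,0.9154441184315818
CGT,1.0781541744465191
CTA,1.0845107971207677
CTC,0.93201812849906684
CTG,0.94694748067182088
CTT,1.0461210343908292
GAA,1.0548530883289366
GAC,0.92966194111232281
GAG,0.94514691167106335
GAT,1.0703380588876772
GCA,1.0816197119304285
GCC,0.93305553039224565
GCG,0.94646254189691092
GCT,1.0388622157804148
GGA,1.089519068361632
GGC,0.9273713218952796
GGG,0.92986043203840341
GGT,1.0532491777046848
GTA,1.0791470907119625
GTC,0.92121431152873146
GTG,0.95482471991326345
GTT,1.0448138778460427
TAC,0.94586587664960953
TAT,1.0541341233503905
TCA,1.0997876857749469
TCC,0.91401273885350309
TCG,0.92038216560509545
TCT,1.085456475583864
TGC,0.91787439613526567
TGT,1.0821256038647342
TTA,1.0573180485203946
TTC,0.9169982418802628
TTG,0.93308451079712085
TTT,1.0830017581197373
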