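probe_id,weight
(Intercept),0.6
cg00000886,-0.138543
cg00003357,0.216877
cg00001721,-0.02962
cg00000025,0.009239
cg00003230,-0.464793
cg00002063,-0.51769
cg00002176,0.605927
cg00001163,0.540399
cg00002710,0.404942
cg00001158,-0.168063
cg00003215,-0.285569
cg00000106,0.038385
cg00002536,-0.311967
cg00001788,0.049488
cg00003692,0.078722
cg00001353,-0.089984
cg00001736,0.599251
cg00003808,0.534664
cg00001552,0.619613
cg00002626,-0.189555
cg00001708,-0.594701
cg00002572,0.246729
cg00003675,-0.296328
cg00000125,0.380275
cg00001804,-0.347296
cg00001891,0.081115
cg00001565,0.277464
cg00001846,-0.45848
cg00001653,0.614376
cg00002504,-0.432407
cg00002024,0.409625
cg00002987,0.385929
cg00003199,-0.705472
cg00003242,0.027372
cg00001069,-0.600441
cg00003198,0.432179
cg00002510,0.152362
cg00001151,0.336596
cg00003260,0.285132
cg00001620,-0.101236
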