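# t_start=                 0
# t_stop=                 4
# n_rows=95
unit_id,time_s
u1,0.14664124790579081
u1,0.31135621480643749
u1,0.33611441776156425
u1,0.3923212718218565
u1,0.64032358676195145
u1,0.78151047974824905
u1,0.84551897365599871
u1,0.95334460772573948
u1,1.0099482974037528
u1,1.1839541038498282
u1,1.2259345157071948
u1,1.2409661011770368
u1, 1.282211727462709
u1,1.2828224515542388
u1,1.3124612392857671
u1,1.3360273260623217
u1,1.5329703036695719
u1,1.5823900233954191
u1,1.6339471628889441
u1,1.6511392872780561
u1,1.7205305602401495
u1,1.7462605033069849
u1,1.8432692512869835
u1,2.0544103067368269
u1,2.2188205812126398
u1, 2.253586039878428
u1,2.2701931707561016
u1,2.2883403161540627
u1,2.3011195827275515
u1,2.3363305423408747
u1,2.3411389151588082
u1,2.5660601705312729
u1,2.5794456358999014
u1, 2.653583625331521
u1,3.0240763733163476
u1,3.2338124308735132
u1,3.2817211383953691
u1,3.5433135833591223
u1,3.8047698931768537
u2,0.23346596397459507
u2,0.26305516064167023
u2,0.30928254406899214
u2,0.37402789574116468
u2,0.69477921072393656
u2,0.73782776854932308
u2,0.96761477738618851
u2,1.0680079311132431
u2,1.2482632454484701
u2, 1.327564837411046
u2,1.3392220390960574
u2,1.3436444206163287
u2,1.4125228710472584
u2, 1.420618848875165
u2,1.4271988403052092
u2,1.4284423217177391
u2,1.4732961328700185
u2,1.6130078947171569
u2,1.6198149211704731
u2,2.1334948986768723
u2,2.3022646810859442
u2,2.5466065052896738
u2, 2.598716133274138
u2,2.6408234862610698
u2,2.6808386882767081
u2,2.8172550359740853
u2,2.9672529567033052
u2,2.9848937094211578
u2,3.0776366731151938
u3,0.86011137906461954
u3,1.0668788924813271
u3,1.1107758888974786
u3,1.2837527543306351
u3,1.2881733775138855
u3,1.7219464024528861
u3,1.7725550523027778
u3, 1.782395894639194
u3,1.7896714173257351
u3,1.8772084945812821
u3,2.1703374637290835
u3,2.2141073774546385
u3,2.2638500537723303
u3,2.2740969220176339
u3,2.2999323531985283
u3,2.3384119663387537
u3, 2.359826878644526
u3,2.3841975582763553
u3,2.4133506799116731
u3, 2.424526309594512
u3,2.4525550808757544
u3,2.4714810708537698
u3, 2.514161984436214
u3,2.7398506011813879
u3, 2.849305990152061
u3,3.0924818702042103
u3,3.9997561490163207
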