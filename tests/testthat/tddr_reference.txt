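0.0167665507695
0.0172228242026
0.0205462323487
0.0176656197431
0.0166099034095
0.0193604544276
0.0165254190266
0.0153610624132
0.0189714342905
0.0175297674171
0.0171555729302
0.0218352024268
0.0214306940807
0.0210313934688
0.0257327728153
0.0254021276265
0.0240059732438
0.0276174860792
0.0263669502675
0.0233410287993
0.0257893872818
0.0243027652986
0.0208467358294
0.0234678511934
0.0231452500085
0.0205316127363
0.0241561106264
0.0253143836974
0.0232587400845
0.026994093721
0.0284793305386
0.025748001918
0.0282439661474
0.0288396162544
0.0246305356449
0.0256272277733
0.025792485144
0.0211324752636
0.0217734465582
0.0226605639184
0.0187329010498
0.0200632283661
0.0224972916325
0.0197278408593
0.0214582719887
0.0245370934983
0.0217047396933
0.022384934627
0.0246871423276
0.0207428018876
0.0198125827708
0.0214321054779
0.0171342734294
0.01559186608
0.0175161075051
0.0139003630725
0.0127698802871
0.0159880231588
0.0139256721269
0.0135362368786
0.0176363769033
0.0161946190321
0.0152320865948
0.0187256733758
0.0165967761281
0.0140659677687
0.016434107211
0.0138280305321
0.0104867940774
0.0127155470716
0.0107935873719
0.00785729227711
0.011099973704
0.0109404656056
0.00907376821053
0.0132367353777
0.0141358411013
0.0122403789902
0.0159927305645
0.016678247884
0.0136109929511
0.0159503688068
0.0159068911367
0.0118221091547
0.0134293635744
0.0138027543237
0.0101230667883
0.0123771632034
0.0144054461847
0.0120038862234
0.0150341643114
0.0181734432598
0.0161367778895
0.0188464021253
0.0220748872521
0.0195071630069
0.0209129468762
0.0233095397074
0.0197066061778
0.0198366606408
0.0220680522162
0.0186816835564
0.0189743785288
0.0224201105835
0.0203921011898
0.0213240374443
0.0256812556204
0.0242828116587
0.0250525104536
0.0297361130229
0.0285139660518
0.0282462211325
0.0319155094402
0.0296909258638
0.0278085741307
0.0303462569791
0.0245469749368
0.0156312010075
0.00986042201727
0.0485078316614
0.0372730852185
0.0336125844703
0.0282084117728
0.0247457074194
0.0291154266038
0.0296023407483
0.0275942225973
0.0309315238651
0.0304623465458
0.0268537341317
0.0288152600681
0.0279320662302
0.0237747268424
0.0256512648241
0.0258011695178
0.0224932562228
0.0252927724306
0.0270145881018
0.0245304268872
0.0275460776565
0.0297174959183
0.0267675412252
0.0285704801169
0.0298865764998
0.0255906068981
0.0258315414449
0.0266386016306
0.021940844063
0.0217016023804
0.0230575655801
0.0190541590728
0.019363601483
0.0221816515602
0.0195175250915
0.0203614116015
0.0239377940378
0.0214942513166
0.0214539138966
0.0243148818542
0.0209229335553
0.0192621580765
0.0212764592704
0.0175155393848
0.0151686782495
0.0173245151362
0.0142569554264
0.0122937712294
0.0156308212285
0.0142265321966
0.0131428001638
0.0174048894229
0.0168414955179
0.0154106179842
0.0191482137131
0.0180867620893
0.0151955429837
0.0176472477946
0.01600259542
0.0122094503437
0.0142988678745
0.0132772868243
0.00990787442197
0.0128836504776
0.013627141268
0.011428035259
0.0152787634744
0.0171467267089
0.0151060449209
0.0186061204057
0.0204189900765
0.0174504997181
0.0195341218283
0.0205515968521
0.0165214557277
0.0176213344954
0.0188438594538
0.0151708245086
0.0167405061558
0.019501791547
0.0172610882778
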