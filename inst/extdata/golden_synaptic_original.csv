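"time_ms","open_probability"
0,0
5,0.1163643065
10,0.223727513
15,0.2646939305
20,0.2715647245
25,0.2643331565
30,0.251745502
35,0.2374308396
40,0.2228932404
45,0.2087556271
50,0.1952686494
55,0.182521743
60,0.1705327518
65,0.1592871289
70,0.1487556854
75,0.1389029353
80,0.1296911678
85,0.121082501
90,0.1130399379
95,0.1055279098
100,0.09851254236
105,0.09196176843
110,0.0858453527
115,0.0801348651
120,0.07480362469
125,0.06982662677
130,0.06518046123
135,0.06084322718
140,0.05679444699
145,0.05301498168
150,0.04948694893
155,0.04619364449
160,0.0431194673
165,0.04024984852
170,0.03757118467
175,0.03507077456
180,0.03273676018
185,0.03055807116
190,0.02852437285
195,0.02662601759
200,0.0248539993
205,0.02319991087
210,0.02165590444
215,0.02021465425
220,0.01886932195
225,0.0176135242
230,0.01644130245
235,0.0153470946
240,0.01432570874
245,0.01337229844
250,0.0124823398
255,0.01165161
260,0.01087616723
265,0.01015233202
270,0.009476669776
275,0.008845974472
280,0.008257253456
285,0.007707713242
290,0.007194746255
295,0.00671591846
300,0.006268957812
305,0.005851743477
310,0.005462295766
315,0.005098766743
320,0.004759431456
325,0.004442679756
330,0.004147008648
335,0.003871015169
340,0.003613389726
345,0.00337290988
350,0.00314843455
355,0.002938898598
360,0.002743307771
365,0.002560733988
370,0.002390310933
375,0.002231229946
380,0.002082736184
385,0.001944125041
390,0.001814738806
395,0.001693963539
400,0.001581226159
405,0.001475991725
410,0.001377760897
415,0.001286067569
420,0.001200476654
425,0.001120582023
430,0.001046004572
435,0.0009763904321
440,0.0009114092817
445,0.0008507527844
450,0.0007941331241
455,0.0007412816394
460,0.0006919475491
465,0.0006458967622
470,0.0006029107668
475,0.0005627855936
480,0.0005253308479
485,0.0004903688064
490,0.0004577335735
495,0.0004272702944
500,0.0003988344205
505,0.0003722910229
510,0.0003475141527
515,0.0003243862434
520,0.0003027975524
525,0.0002826456412
530,0.0002638348886
535,0.0002462760371
540,0.0002298857697
545,0.0002145863144
550,0.000200305075
555,0.0001869742866
560,0.0001745306945
565,0.0001629152537
570,0.0001520728486
575,0.0001419520318
580,0.00013250478
585,0.0001236862656
590,0.0001154546448
595,0.0001077708583
600,0.0001005984464
605,9.390337588e-05
610,8.765387856e-05
615,8.182030043e-05
620,7.637496108e-05
625,7.129202225e-05
630,6.654736533e-05
635,6.211847683e-05
640,5.79843416e-05
645,5.412534309e-05
650,5.052317029e-05
655,4.716073082e-05
660,4.402206985e-05
665,4.109229437e-05
670,3.835750256e-05
675,3.580471777e-05
680,3.3421827e-05
685,3.119752339e-05
690,2.912125257e-05
695,2.718316261e-05
700,2.537405724e-05
705,2.368535221e-05
710,2.21090346e-05
715,2.063762475e-05
720,1.926414079e-05
725,1.798206551e-05
730,1.678531546e-05
735,1.566821202e-05
740,1.462545452e-05
745,1.365209507e-05
750,1.274351504e-05
755,1.189540322e-05
760,1.11037353e-05
765,1.036475479e-05
770,9.674955235e-06
775,9.031063508e-06
780,8.430024337e-06
785,7.86898578e-06
790,7.345285699e-06
795,6.856439128e-06
800,6.400126481e-06
805,5.974182548e-06
810,5.576586215e-06
815,5.205450883e-06
820,4.859015507e-06
825,4.535636245e-06
830,4.233778656e-06
835,3.952010423e-06
840,3.688994548e-06
845,3.443483017e-06
850,3.214310874e-06
855,3.000390693e-06
860,2.800707418e-06
865,2.614313549e-06
870,2.440324644e-06
875,2.277915123e-06
880,2.126314349e-06
885,1.984802974e-06
890,1.852709524e-06
895,1.729407214e-06
900,1.614310971e-06
905,1.506874662e-06
910,1.4065885e-06
915,1.312976625e-06
920,1.225594848e-06
925,1.144028539e-06
930,1.067890667e-06
935,9.968199537e-07
940,9.304791691e-07
945,8.685535246e-07
950,8.107491818e-07
955,7.567918582e-07
960,7.064255253e-07
965,6.594111939e-07
970,6.155257803e-07
975,5.745610474e-07
980,5.363226167e-07
985,5.006290463e-07
990,4.673109696e-07
995,4.362102916e-07
1000,4.071794392e-07
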