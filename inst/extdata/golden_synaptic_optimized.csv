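"time_ms","open_probability"
0,0
5,0.125011484
10,0.2429484675
15,0.2882324237
20,0.2942965485
25,0.2845452165
30,0.2693323354
35,0.2527758284
40,0.2364444184
45,0.2209024056
50,0.2063230028
55,0.1927288459
60,0.1800860895
65,0.1683412256
70,0.1574354841
75,0.1473104343
80,0.1379101143
85,0.1291817797
90,0.1210760955
95,0.1135471002
100,0.106552076
105,0.1000513813
110,0.09400826853
115,0.08838870056
120,0.08316117006
125,0.07829652539
130,0.07376780442
135,0.06955007714
140,0.06562029753
145,0.06195716457
150,0.05854099237
155,0.05535358906
160,0.05237814415
165,0.04959912389
170,0.04700217418
175,0.04457403064
180,0.04230243533
185,0.04017605974
190,0.0381844335
195,0.03631787857
200,0.03456744842
205,0.03292487179
210,0.0313825009
215,0.02993326347
220,0.02857061855
225,0.02728851571
230,0.02608135736
235,0.02494396401
240,0.02387154221
245,0.02285965493
250,0.02190419429
255,0.02100135634
260,0.02014761783
265,0.01933971475
270,0.01857462254
275,0.01784953786
280,0.01716186169
285,0.01650918382
290,0.01588926849
295,0.01530004116
300,0.01473957628
305,0.01420608602
310,0.0136979099
315,0.0132135051
320,0.0127514377
325,0.01231037444
330,0.01188907515
335,0.01148638586
340,0.01110123227
345,0.01073261387
350,0.01037959844
355,0.01004131697
360,0.009716959018
365,0.009405768342
370,0.009107038949
375,0.008820111395
380,0.008544369386
385,0.008279236629
390,0.008024173934
395,0.007778676522
400,0.007542271549
405,0.007314515812
410,0.00709499363
415,0.006883314887
420,0.006679113215
425,0.006482044325
430,0.006291784455
435,0.006108028938
440,0.005930490874
445,0.005758899908
450,0.005593001089
455,0.005432553824
460,0.005277330903
465,0.005127117595
470,0.004981710821
475,0.004840918372
480,0.004704558201
485,0.004572457752
490,0.004444453347
495,0.004320389615
500,0.004200118965
505,0.004083501087
510,0.003970402505
515,0.003860696145
520,0.003754260947
525,0.003650981497
530,0.003550747689
535,0.003453454405
540,0.003359001226
545,0.003267292155
550,0.003178235362
555,0.00309174295
560,0.003007730731
565,0.00292611802
570,0.002846827446
575,0.002769784769
580,0.002694918711
585,0.002622160807
590,0.00255144525
595,0.002482708761
600,0.002415890455
605,0.002350931729
610,0.00228777614
615,0.002226369309
620,0.002166658816
625,0.00210859411
630,0.002052126422
635,0.001997208683
640,0.001943795444
645,0.00189184281
650,0.001841308367
655,0.001792151118
660,0.001744331424
665,0.001697810946
670,0.001652552591
675,0.001608520462
680,0.001565679807
685,0.001523996976
690,0.001483439377
695,0.001443975433
700,0.001405574547
705,0.00136820706
710,0.001331844222
715,0.00129645815
720,0.001262021807
725,0.001228508961
730,0.001195894165
735,0.001164152724
740,0.00113326067
745,0.001103194738
750,0.001073932342
755,0.00104545155
760,0.001017731067
765,0.0009907502058
770,0.0009644888761
775,0.0009389275589
780,0.0009140472908
785,0.0008898296455
790,0.0008662567168
795,0.0008433111025
800,0.0008209758887
805,0.0007992346344
810,0.0007780713572
815,0.0007574705193
820,0.0007374170139
825,0.0007178961525
830,0.0006988936519
835,0.0006803956225
840,0.0006623885567
845,0.0006448593174
850,0.0006277951272
855,0.0006111835581
860,0.0005950125213
865,0.000579270257
870,0.0005639453257
875,0.0005490265983
880,0.0005345032478
885,0.0005203647402
890,0.0005066008268
895,0.0004932015354
900,0.0004801571634
905,0.0004674582695
910,0.0004550956666
915,0.000443060415
920,0.0004313438152
925,0.0004199374013
930,0.0004088329348
935,0.0003980223978
940,0.0003874979873
945,0.0003772521094
950,0.0003672773733
955,0.0003575665856
960,0.0003481127454
965,0.0003389090388
970,0.0003299488335
975,0.0003212256744
980,0.0003127332783
985,0.0003044655297
990,0.000296416476
995,0.0002885803229
1000,0.0002809514306
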