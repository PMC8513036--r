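composition,isomer_index,rt_min,baseline_mean_pct,rsd_pct
N4H5S,1,43.69,0.880960246668869,30
N4H5S,2,44.1,0.6607201850016516,30
N4H5S,3,44.51,0.4404801233344345,30
N4H5SF,1,44.83,0.44598612487611494,30
N4H5SF,2,45.08,0.3716551040634291,30
N4H5SF,3,45.32,0.2973240832507433,30
N4H5SF,4,45.56,0.22299306243805747,30
N4H5SF,5,45.81,0.14866204162537164,30
N4H5SF2,1,46.54,0.2973240832507433,30
N4H5S2,1,61.65,9.69056271335756,30
N4H5S2,2,62.23,7.267922035018168,30
N4H5S2,3,62.81,4.84528135667878,30
N4H5S2F,1,63.54,1.7839444995044598,30
N4H5S2F,2,64.41,1.189296333002973,30
N4H5S2F2,1,65.28,0.47571853320118934,30
N4H5S2F2,2,66.16,0.31714568880079286,30
N5H6S2,1,66.74,2.5694673861175343,30
N5H6S2,2,67.03,2.202400616672173,30
N5H6S2,3,67.32,1.8353338472268106,30
N5H6S2,4,67.61,1.4682670777814484,30
N5H6S2,5,67.9,1.1012003083360864,30
N5H6S2,6,68.19,0.7341335388907242,30
N5H6S2F,1,68.55,1.0618717258955117,30
N5H6S2F,2,68.99,0.8494973807164093,30
N5H6S2F,3,69.42,0.6371230355373071,30
N5H6S2F,4,69.86,0.4247486903582047,30
N5H6S2F2,1,70.51,0.47571853320118934,30
N5H6S2F2,2,71.39,0.31714568880079286,30
N6H7S2,1,72,1.189296333002973,30
N6H7S2,2,72.35,0.9910802775024776,30
N6H7S2,3,72.69,0.7928642220019821,30
N6H7S2,4,73.04,0.5946481665014866,30
N6H7S2,5,73.39,0.39643211100099107,30
N6H7S2F,1,73.86,0.6607201850016516,30
N6H7S2F,2,74.44,0.4955401387512388,30
N6H7S2F,3,75.02,0.3303600925008258,30
N5H6S3,1,83.63,4.111147817788055,30
N5H6S3,2,83.96,3.523840986675476,30
N5H6S3,3,84.3,2.9365341555628968,30
N5H6S3,4,84.63,2.3492273244503172,30
N5H6S3,5,84.96,1.761920493337738,30
N5H6S3,6,85.3,1.1746136622251586,30
N5H6S3F,1,85.72,1.4158289678606824,30
N5H6S3F,2,86.22,1.1326631742885458,30
N5H6S3F,3,86.72,0.8494973807164093,30
N5H6S3F,4,87.22,0.5663315871442729,30
N5H6S3F2,1,87.8,0.6607201850016516,30
N5H6S3F2,2,88.47,0.4955401387512388,30
N5H6S3F2,3,89.14,0.3303600925008258,30
N5H6S3F3,1,89.98,0.35678889990089196,30
N5H6S3F3,2,90.98,0.23785926660059464,30
N6H7S3,1,91.65,2.0555739088940275,30
N6H7S3,2,91.98,1.761920493337738,30
N6H7S3,3,92.32,1.4682670777814484,30
N6H7S3,4,92.65,1.1746136622251586,30
N6H7S3,5,92.98,0.880960246668869,30
N6H7S3,6,93.32,0.5873068311125793,30
N6H7S3F,1,93.74,1.0618717258955117,30
N6H7S3F,2,94.24,0.8494973807164093,30
N6H7S3F,3,94.74,0.6371230355373071,30
N6H7S3F,4,95.24,0.4247486903582047,30
N6H7S3F2,1,95.82,0.4404801233344345,30
N6H7S3F2,2,96.49,0.3303600925008258,30
N6H7S3F2,3,97.16,0.22024006166721724,30
N7H8S3,1,97.83,0.3523840986675476,30
N7H8S3,2,98.5,0.26428807400066073,30
N7H8S3,3,99.17,0.1761920493337738,30
N6H7S4,1,99.89,1.4190467609694566,30
N6H7S4,2,100.07,1.261374898639517,30
N6H7S4,3,100.24,1.1037030363095774,30
N6H7S4,4,100.42,0.9460311739796378,30
N6H7S4,5,100.6,0.7883593116496982,30
N6H7S4,6,100.78,0.6306874493197585,30
N6H7S4,7,100.96,0.4730155869898189,30
N6H7S4,8,101.13,0.31534372465987925,30
N6H7S4F,1,101.36,0.8919722497522299,30
N6H7S4F,2,101.65,0.7433102081268582,30
N6H7S4F,3,101.93,0.5946481665014866,30
N6H7S4F,4,102.22,0.44598612487611494,30
N6H7S4F,5,102.5,0.2973240832507433,30
N6H7S4F2,1,102.88,0.5285761480013215,30
N6H7S4F2,2,103.36,0.39643211100099107,30
N6H7S4F2,3,103.83,0.26428807400066073,30
N6H7S4F3,1,104.42,0.2973240832507433,30
N6H7S4F3,2,105.13,0.19821605550049554,30
N7H8S4,1,105.61,0.6423668465293836,30
N7H8S4,2,105.84,0.5506001541680432,30
N7H8S4,3,106.08,0.45883346180670265,30
N7H8S4,4,106.32,0.3670667694453621,30
N7H8S4,5,106.56,0.2753000770840216,30
N7H8S4,6,106.79,0.18353338472268105,30
N7H8S4F,1,107.09,0.4247486903582047,30
N7H8S4F,2,107.44,0.33979895228656376,30
N7H8S4F,3,107.8,0.2548492142149228,30
N7H8S4F,4,108.16,0.16989947614328188,30
N7H8S4F2,1,108.69,0.2973240832507433,30
N7H8S4F2,2,109.4,0.19821605550049554,30
N8H9S4,1,109.99,0.3523840986675476,30
N8H9S4,2,110.47,0.26428807400066073,30
N8H9S4,3,110.94,0.1761920493337738,30
N8H9S4F,1,111.53,0.23785926660059467,30
N8H9S4F,2,112.24,0.15857284440039643,30
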