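wavelength_nm,eps_hbo2,eps_hb,mua_melanosome
400,412482,183118,1497.2
401,433325,192072,1484.25
402,454212,202540,1471.44
403,474856,214805,1458.77
404,494954,229216,1446.24
405,514197,246179,1433.86
406,532270,266116,1421.6
407,548863,289407,1409.48
408,563682,316279,1397.5
409,576449,346687,1385.64
410,586917,380178,1373.92
411,594871,415782,1362.32
412,600140,451975,1350.85
413,602595,486742,1339.5
414,602157,517763,1328.27
415,598801,542721,1317.17
416,592552,559685,1306.18
417,583486,567498,1295.32
418,571730,566062,1284.56
419,557456,556466,1273.93
420,540875,540875,1263.4
421,522236,522214,1252.99
422,501811,503684,1242.69
423,479898,488225,1232.49
424,456802,478051,1222.41
425,432837,474333,1212.43
426,408313,477108,1202.55
427,383529,485395,1192.78
428,358772,497476,1183.11
429,334304,511250,1173.54
430,310365,524582,1164.07
431,287163,535564,1154.7
432,264878,542679,1145.42
433,243656,544834,1136.24
434,223611,541325,1127.16
435,204827,531747,1118.17
436,187356,515914,1109.27
437,171223,493809,1100.46
438,156429,465585,1091.74
439,142952,431619,1083.11
440,130753,392585,1074.57
441,119776,349530,1066.11
442,109953,303907,1057.74
443,101210,257533,1049.46
444,93464,212477,1041.25
445,86631,170859,1033.13
446,80625.4,134610,1025.09
447,75363,105227,1017.14
448,70762.3,83573.2,1009.26
449,66746,69778.3,1001.46
450,63241.6,63241.6,993.732
451,60182.3,62750.9,986.085
452,57507.1,66694.9,978.514
453,55161.2,73303.2,971.018
454,53095.9,80890.3,963.595
455,51268,88046.2,956.245
456,49640.3,93753.3,948.967
457,48180.2,97422.2,941.761
458,46860.1,98857.7,934.624
459,45656.6,98176.4,927.557
460,44549.9,95703,920.559
461,43523.6,91867.3,913.629
462,42564,87119.6,906.765
463,41660,81870.8,899.968
464,40802.4,76459.1,893.236
465,39983.9,71137.8,886.569
466,39198.6,66079.5,879.966
467,38441.6,61388.1,873.426
468,37709.2,57114.4,866.949
469,36998.4,53271.6,860.533
470,36306.8,49848,854.178
471,35632.5,46817.4,847.883
472,34974.1,44145.8,841.649
473,34330.4,41796.6,835.472
474,33700.4,39733,829.355
475,33083.4,37919.9,823.294
476,32478.7,36325.1,817.291
477,31886,34919.1,811.344
478,31304.7,33675.8,805.452
479,30734.5,32572,799.616
480,30175.1,31587.3,793.833
481,29626.2,30704.3,788.105
482,29087.6,29907.7,782.43
483,28559,29184.8,776.807
484,28040.3,28524.3,771.236
485,27531.2,27916.9,765.716
486,27031.5,27354.1,760.247
487,26541.2,26828.5,754.828
488,26059.9,26333.2,749.459
489,25587.6,25861.1,744.139
490,25124.2,25405.8,738.867
491,24669.4,24960.4,733.644
492,24223.3,24518.6,728.468
493,23785.7,24075.1,723.339
494,23356.7,23625.9,718.256
495,22936.2,23169.5,713.219
496,22524.3,22707.7,708.227
497,22121.3,22245.7,703.281
498,21727.5,21792.9,698.378
499,21343.3,21362.3,693.52
500,20969.4,20969.4,688.705
501,20606.9,20631.1,683.933
502,20256.8,20363.3,679.204
503,19921,20179.7,674.516
504,19601.6,20089.4,669.87
505,19301.4,20096.4,665.265
506,19023.7,20199,660.701
507,18773,20390.2,656.177
508,18554.4,20659.3,651.693
509,18374.2,20993.5,647.248
510,18239.7,21380,642.843
511,18159.7,21807.5,638.475
512,18143.9,22267.9,634.146
513,18203.7,22756.4,629.855
514,18351.3,23272,625.601
515,18600.3,23816.7,621.384
516,18965,24394.8,617.203
517,19460.2,25011.9,613.058
518,20101.1,25673.8,608.95
519,20902.3,26385.9,604.876
520,21877.4,27152.9,600.838
521,23038.4,27978.2,596.834
522,24394.8,28864,592.865
523,25952.5,29811.4,588.929
524,27713.6,30820.3,585.027
525,29675.1,31889.8,581.158
526,31828.2,33017.9,577.323
527,34158.1,34202,573.519
528,36643,35438.8,569.748
529,39254.7,36724.2,566.009
530,41958.2,38053.4,562.301
531,44712.1,39421.2,558.625
532,47469.7,40821.6,554.979
533,50180,42248,551.364
534,52788.7,43693.3,547.779
535,55240.2,45149.8,544.224
536,57479.5,46609.6,540.699
537,59453.6,48064.1,537.203
538,61114,49504.3,533.736
539,62418.3,50921.3,530.298
540,63332,52305.7,526.888
541,63830.2,53648,523.507
542,63898.4,54938.9,520.153
543,63533.7,56168.9,516.827
544,62744.9,57329,513.529
545,61552.9,58410.1,510.257
546,59989.6,59403.9,507.012
547,58097.9,60302.1,503.794
548,55929.9,61097.5,500.602
549,53545.8,61783,497.436
550,51012.2,62352.6,494.296
551,48400.4,62800.9,491.181
552,45784.5,63123.6,488.091
553,43239.3,63317.2,485.026
554,40838.7,63378.9,481.987
555,38653.8,63307.3,478.971
556,36751,63101.8,475.98
557,35190.1,62762.7,473.013
558,34022.6,62291.4,470.069
559,33290.4,61690.1,467.149
560,33023.8,60961.6,464.253
561,33239.9,60109.7,461.379
562,33942.1,59138.4,458.529
563,35118,58052.6,455.701
564,36739.8,56858.2,452.895
565,38763.5,55562.9,450.112
566,41129.6,54178.5,447.35
567,43764,52723.1,444.611
568,46579.9,51225.3,441.893
569,49480.5,49728.6,439.196
570,52362,48295.5,436.52
571,55117.4,47008.5,433.866
572,57640.8,45967.9,431.232
573,59832.2,45281.9,428.618
574,61601,45048.8,426.025
575,62871.1,45334,423.453
576,63583.5,46142.7,420.9
577,63699.7,47398.5,418.367
578,63202.5,48932.1,415.853
579,62097.2,50489.6,413.359
580,60410.6,51762,410.884
581,58189,52431.9,408.428
582,55495.9,52230.7,405.991
583,52407.9,50989.7,403.573
584,49010.9,48675.2,401.173
585,45395.7,45395.7,398.792
586,41653.5,41380.4,396.429
587,37872.4,36935,394.084
588,34133.4,32386.2,391.756
589,30508,28028,389.446
590,27056.1,24083.4,387.154
591,23824.9,20684.9,384.879
592,20848.6,17876.8,382.622
593,18148.7,15631.1,380.381
594,15735.2,13873.2,378.157
595,13607.8,12506.7,375.95
596,11757.6,11434.2,373.759
597,10169.2,10571.1,371.585
598,8822.29,9851.31,369.427
599,7693.38,9228.33,367.285
600,6757.57,8672.15,365.159
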