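wavelength_nm,M01,M02,M03,M04,M05,M06,O01,O02,O03,O04,O05,O06
490,0.123537974511844,0.127307981300659,0.0876722615009347,0.120645889277431,0.118630895788879,0.0643108619799858,0.110340392533944,0.130729037970522,0.139431455876137,0.0888806635656391,0.140381360435268,0.0738649093572973
560,0.160177580203402,0.1602912080122,0.112678324492137,0.156171863031983,0.158847114741251,0.0971225026385514,0.143110886587932,0.164200109788652,0.171833703219123,0.122544449641683,0.171377426735097,0.104452124834954
665,0.197936656238903,0.217702367568817,0.169620855906723,0.193447671356652,0.189136032774236,0.15234557308872,0.200473360695695,0.228041727114881,0.224045309576559,0.162404499942048,0.22947398153236,0.152485080827428
705,0.261190666253817,0.265685683661101,0.215312983948464,0.252142921700784,0.252437532013882,0.218414735211142,0.253757911515804,0.273368687271651,0.266573138259022,0.233457714364968,0.269049474413109,0.220451174198592
740,0.322584665589497,0.314205228814273,0.256138276593973,0.312508331983026,0.328470752500507,0.284155026426422,0.303568094901436,0.314628990457868,0.305156651698483,0.303644268401797,0.304342965375436,0.280221359719097
783,0.370070800166094,0.356134018961092,0.294383568077657,0.361376540502031,0.385314058783859,0.338459258903179,0.349926910304425,0.354959241307665,0.342720501875121,0.36288503920665,0.337895602735495,0.334889255358923
842,0.394383596623726,0.384597849809918,0.320391477239127,0.385617624605152,0.409493779222361,0.367234680669451,0.379296330799178,0.384598766224475,0.370840187033194,0.392737737656972,0.366519970080052,0.366745120973266
865,0.404994213492196,0.396185888615593,0.331851016944337,0.396506451865716,0.420241244201245,0.379934598352985,0.391786895445095,0.397371071235969,0.382181608728586,0.405502151996688,0.378392903716517,0.380993287266197
1610,0.419480402391557,0.416991984026199,0.339756617833149,0.41065576256678,0.432053239746349,0.364119077452168,0.405661070904911,0.421217184927171,0.416293837435534,0.407620265684179,0.414109298226428,0.38372246184685
2190,0.366403411858493,0.35657801352592,0.2641958669724,0.359572001056837,0.375808910123105,0.281219424718366,0.350516082644319,0.366476486565868,0.374268653259044,0.348296544045267,0.358036749075846,0.292014893806447
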