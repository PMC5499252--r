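0.176718677375832,-0.300733138517896,-0.917245566604548,0.305972846437371,-2.70634207884421,1.42701261373797,-1.04130307658146,0.657946471023434,0.322434559548429,0.303972743853598,0.920287936586199,-0.258167718267166,-0.83422697085543,-0.605206568943956,-0.0116685331277413,-0.378180173964711
-0.390410254130793,0.571333939397081,-0.261810308430073,-0.620688860677079,-0.280116249720335,-0.0108324255414598,-0.20811474915542,-0.63429618185185,1.02943811659304,0.773346900639363,-0.314284266313454,-0.278063142529671,-3.22179670258166,0.688681459135495,0.0324028540399721,0.860419763183204
1.26666366792029,-0.365513805592332,-1.511927730699,-0.864126563227472,0.580180955891878,-0.396703263099403,1.17603272972484,1.48883930730856,-0.888649300164552,-0.0373773157685608,-0.0739730119780384,-0.0273412194846828,0.657461800064135,-0.265446978328544,0.795240537286285,1.19914578064969
-0.680996121957682,-0.180520948349997,-0.0785397320826037,0.449777826214187,0.474463991586041,0.415834791293683,0.815480146393758,0.0807108191150275,-0.357185253451531,0.737979688447397,-0.882723366658864,-0.151414016145453,1.58483938725574,0.348922456094999,-0.759848274078063,-0.0246231031527733
0.862588284293403,1.96821115703263,-2.36622052078698,0.100131130553442,-0.57870989206247,-2.37928774693174,0.535753632000328,-0.707260360302716,-0.799684796209661,-0.0164186028335335,0.185063086224506,0.431708345760113,-0.143837073111904,2.01139399197733,0.0739406165879832,0.259430463970643
-0.634645105574142,-1.81306282386336,0.171091377987177,0.319644907678008,-0.110295849355756,2.66059982935468,0.309379966694512,0.37977490225551,-0.867502467442941,-1.88003376747981,-0.334176750802443,-1.6663773804316,1.12395688732878,-0.0333067550838925,-1.31783373928785,0.575379695071198
-1.27821917820127,-0.122581455184333,-1.44512318843639,1.25088649641712,2.31019663516723,-0.725270482848674,-2.26658634148277,0.418319774212334,-0.0622266211050502,-2.10835090204174,-1.85827821335762,-1.92020196069755,-2.05656419081349,-0.913946048244432,1.05099067072049,0.958175231041807
0.660141052678215,-0.270308794023782,-0.530967177639375,-0.541597062753452,0.711855552736674,-0.915084266427596,1.17880005904057,0.966053515521797,-0.214310551739416,-0.542903263968052,0.624606702461802,2.01814738161982,-1.98724589029471,0.727928543360294,1.08190405281932,-0.397073624800271
1.13785380127835,-0.764492752579557,-1.38218193384692,-0.524096306149829,0.258973376918909,-0.677586622079513,-0.554828994424154,1.55214133604555,1.57664968288713,1.09535478072589,0.668063102437066,0.708313881029035,-0.228545408837469,1.13378603002399,0.138829635657666,0.897298871760587
-0.628640024894189,0.955636346229857,0.515206541813918,0.730873622138105,1.2693877058813,0.0184180905234291,0.111563964957048,-1.63455746234587,1.26799125621947,1.21903105934282,-0.138073818007746,0.80719941168034,1.18562926881666,-0.598750305259838,-0.000172018055809708,-0.461811018652224
0.963082591206251,0.77930670719341,1.61320518777635,-1.02088195542292,0.0379818725222933,-0.554670396857305,-1.04876600433524,0.309799339879923,0.562846901849878,0.841214791061175,-0.517891367758422,1.30288956895831,-0.697130975563942,2.17398170990132,-0.086097732135708,-0.417724169001197
0.456504843096176,-0.473382530804645,-0.491099521384319,0.421486012138467,0.773112886808886,0.791300596433741,0.368094011043125,1.07224941007992,-0.12386220744615,-0.899094105860086,0.60265584882219,0.481637791342848,0.572446490416444,-1.63219864383999,-1.33170822234922,-0.230787179230562
0.31991114829142,0.929114544877135,0.391225139595329,-0.0538560099799145,-0.052955445676371,-1.95950321048795,-0.414220298925065,0.555904217016359,0.56189248117354,-0.711379033635941,-0.690457941756841,-0.240830349808542,0.775960943810532,0.546170307321114,0.328790123510088,0.26420666717319
-0.303557157063391,0.100397359859349,-0.157700199467182,-1.21914969013319,-1.01002389054093,-0.920464860496177,-1.48062342690004,-1.65116319917786,-3.38754726783042,0.0770135116526792,-0.83544408644064,0.178622222322064,-3.75802439547867,-1.57424950785909,-2.32484909008661,-0.384818799936287
-1.15741447445042,-0.356751850239933,0.761015902716606,-1.01751867007149,0.0723545921869358,-0.985053123191603,-0.130942951169376,0.27170358137492,-1.14408092720349,-0.355330012370456,0.187183284252976,0.22012270320923,-2.28266077839881,0.999357109885809,-0.460599154909416,0.650531344620291
0.147051488313245,-0.496107248406451,-1.02962801015815,-0.189727923403443,-1.7695053077803,-0.140093640178604,0.984719639653723,-1.79007202602576,0.192680799503754,-0.304284578076243,1.77732839231513,-0.379720315561583,0.834177730392346,-0.592240885268028,0.448772092002432,0.418314368853496
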