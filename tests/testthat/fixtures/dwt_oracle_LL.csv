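0.263000425537027,-1.27143938136122,-1.12722474821579,-0.182626441241065,0.26673590456028,1.74934012469436,1.44682579333203,-0.365704497356366,2.11894814389987,-2.35475632400811,0.452697210669906,-0.529898935860442,0.565425135594937,-0.240252204932815,-0.221868836911263,-1.22443935688732
1.21851369529483,-0.44668704627929,0.169131892042318,-0.350545055059326,-0.162339692905969,0.421981401819493,-0.80162398665038,0.0058675773149276,-0.401116029219576,0.18668458070886,-0.429020694601299,-0.766101005364081,-0.0784786660687927,-0.752487371028246,-1.33051869733296,0.336411014526713
2.09540941300996,0.305053802998713,-0.291423395317509,-1.09473282581024,-0.460988372098372,0.0281972319134318,0.643519729695228,-0.212230764590682,-1.51695534486211,0.160369714256866,0.243150208979701,0.78508145204154,0.863766381115102,1.02842141680297,-0.660485808324384,-0.695911144589892
-0.968759297768569,0.500734357706,-0.220453907635674,-1.28572388437262,1.24146857737689,0.017273603961966,1.46682469662839,1.31974364322232,0.245389166640755,-0.33470348893368,0.914266380005462,-1.23504867854456,0.511783605508521,-0.00843808345066266,-1.45145006781773,-0.0814315963984303
-1.768951354018,-0.914530011787795,-1.70828096283586,-1.13576250775027,-0.697153567169546,0.417499666591415,0.587159426191742,0.145590563885121,-0.633019153440451,0.620388546710249,-0.209340940880424,-0.134393693683619,0.230377478199322,0.0560424167773875,-0.160626903392754,0.857732684651964
0.624026590467593,1.01098013041599,2.34766745095641,-2.30225673608386,-2.43902588983667,0.516424584286432,-0.048859649903861,0.529416492467353,0.811342105999507,-0.373873207155406,-1.51867643069733,-0.968996827186691,-1.47776477917211,-0.985226143437206,-0.734369220416343,0.970791429656304
1.4866181202366,-0.30469591728668,0.241770083656279,0.0336400039771503,0.479794067057478,0.595840732114695,-0.690416470412667,1.27528345176073,1.18338074577254,-0.527643668704985,2.11154831396791,-1.40223374349834,0.877573097753806,0.339339425177198,0.104786204356557,0.214768666900102
0.791495291377991,1.09542300253841,0.082211876245083,-1.89019761945945,-0.571153251006369,-0.396849239899895,0.723718559685484,-0.905183963298559,-0.832850183810264,0.676831618737709,-0.769636499174684,0.865350351219611,0.309225191118653,-0.873652062997328,-1.22099026962011,0.548608350957321
-0.862695620576613,1.16840965793082,-0.072409823115859,-0.161519659814404,-0.892094870805274,0.8435138937937,2.50801585464476,0.552758731625109,-1.31153613012772,-0.669153100515395,0.193199381123017,2.18466237686736,-0.253043036621526,-0.15121474692592,0.0155847183814256,-0.642678190272121
1.17172514088496,-2.18173950599147,0.0123367492739373,0.551498682487477,-0.58701465597899,1.14058460428761,0.169549512345721,-0.154603543390672,-0.953394718346874,-0.661683531677192,-0.342984270148411,-0.333764751663241,-0.817935556983073,-0.377688159395454,0.936427344887825,-0.680190785795836
0.572711094602428,-0.14390458718319,1.81394335369306,-0.946475466844466,-2.44509461615183,0.478413472855848,-0.211204226543086,1.28277643685051,-0.0402984989984082,1.36738924866918,0.881301937745669,1.64723089849608,-0.795117468369903,-0.00406149095196671,0.9628380417669,0.579893770314827
-0.37028155700407,2.55175790759413,-0.789246440290554,0.552995140014299,-0.462007346146902,-0.346237281085531,-0.403830078634901,-0.431543567302651,0.679580712907013,-0.436920551855024,-0.628299507181912,-1.42493079604983,1.17633224491094,0.178332908476817,-0.0065023280263326,0.267565531819045
0.735413529796135,0.744800501395488,-0.949507734961329,0.772524456069632,-0.594969248561631,0.760048138454967,1.37585528817143,-0.157634361512119,0.0959332503478295,0.0806701185398513,-0.3171652394808,-0.383207092961214,0.0476453921038992,-0.730141620042251,1.22028210694312,-0.961243377542059
0.491729649827727,1.93784738553456,0.703298389398696,0.995148234637538,-0.477138144866716,1.2535349041311,0.630397583500297,0.136691885029764,1.95383244213605,-0.710065959299997,0.739597384370984,1.42345427920211,2.60379674245692,-1.79360745604286,1.15121992677302,-0.548160463109635
-0.341716905954375,2.53580509584592,0.0646653043724209,0.512330311602036,0.944462558043706,0.940911709763312,-1.15057054733413,-0.103306182686784,-0.247053134988513,-0.962631201081886,1.21844263722343,-0.477449758049633,-1.07156843535904,-1.6942529196121,-1.7761449403893,1.94674693227749
-2.69816905454446,0.251027016279294,0.483028594767357,0.828355907811651,-1.04997188482882,0.560499936890637,1.01529801403734,2.10167666566147,0.39220102710664,0.0730403041298904,0.598262665531161,0.248611565295046,0.147877534928754,0.665135397293218,0.346080806998548,0.909974202134821
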