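-0.0772525953471906,1.30782531687973,0.322649295064173,-0.675067322319456,2.29553107977824,-0.0775599562919114,-0.0853410518339644,1.85192670481218,0.373156266846404,-0.284478189465367,0.720636528472064,1.93022997900484,-0.447857892667138,0.727129191970733,1.09502996904524,-0.850380910680388
0.0131851171389503,-0.00116423962939537,0.333668674789169,-1.25580025706537,-0.368498392517752,0.329808302821418,-0.986759819389642,0.264293520582807,-0.115790015834931,0.0223962272722531,-0.058041561883345,0.219807287530284,-1.48536712604211,1.39325468662535,0.831439359345947,-0.954232809559131
-0.592082593743236,-0.194303357534504,-0.305822773084809,-0.711385568952326,-0.740985804611258,1.1455719246728,2.0526007627178,-0.812740113259002,1.76884587729052,-0.100282382300251,-0.301011770398209,0.0300220813948733,-1.39076827705703,-0.324241095914682,-0.285623272195972,-1.05624975573343
0.14820433946101,-0.821631747687838,-0.930783346540742,0.905675771122854,-0.929134473930529,-0.279952883644204,-0.0382995313000162,1.21371987460944,-0.558329152569138,-1.21228423525202,0.0756027491496223,0.0276412564693057,0.382992476424728,1.95700599568329,0.704242131677276,-0.0709831497531814
1.18116196626494,-0.0874901684514934,0.844145136221754,0.447240743502153,-0.734938032991332,-2.52817702301583,-0.445713121433163,1.21666866409263,0.398827515309528,0.417655395381779,1.74272438246411,-0.650547030443333,0.379251059557862,-0.92510542352261,-0.308261838183863,-0.555076641267799
-0.665698899969589,-0.483952996217383,0.266398065978899,-0.180992791391091,-0.291918906000681,0.141986808044657,0.728791394716041,-0.370182572302593,-0.675454677904609,-0.26027163249437,-0.845958297622956,-0.972762061561592,1.03842419307708,-0.365426344173332,1.25941184820647,-0.0986363227560687
0.466533037770835,0.186252268268474,-0.409243406246266,1.76065671539506,-0.530574542218056,0.531225442258426,0.375127343555527,-1.18508584709288,-0.447252881765432,0.155420046032386,-0.155661339416107,0.53747283285646,-0.021476302106928,-0.705939762715206,-0.0555678370469336,0.315840423507999
0.374308372517043,0.927529922386598,1.22048333626511,0.471606681062208,1.01770474545687,-0.535195166670015,-1.3041281312616,-0.876115363800474,-0.0648190128889477,-1.42481919768739,2.26921053271659,-0.240989965576258,-0.856407404863528,0.693074086876061,0.215041104196531,0.0252572184092234
-0.587223445805501,0.683380824060119,-0.665267879626275,1.06109112569624,-0.686592320481891,0.232692363260581,0.518517961249236,1.44817346960342,-1.05216067012238,0.300701476122962,0.317231764734119,-0.699165440921224,2.07001570302506,-1.45084876511191,1.11771199982482,-1.94745907565554
-1.59644601883489,-1.93338866832541,1.1184694413658,-0.514775348259418,-0.849043471159968,-0.852317540967405,-0.715797073554929,-2.20063478659371,-1.3616444461209,-0.11899016342822,0.25052861459344,1.06221376335246,1.40418001459478,-0.979307749636368,1.22984173531523,-1.09819881054631
-0.408646772003965,-1.89646625513543,0.0847573864278746,0.752544489903231,-1.31433151210022,-0.73209444232472,0.083153603936961,-0.925898276176933,0.674856510809079,0.577355026154975,-0.0555865299817612,0.455976062828738,0.621692641317998,-1.22556386339127,-0.847885401923136,-0.552262377045328
-0.0286054740083971,-1.9526602615555,-0.624061464085743,0.229657545164312,0.443380479291258,0.729097017299867,0.79655358401039,-2.21105328192496,-0.670181767318089,0.100443306838972,0.169780625205497,-0.931415979787014,-0.667235580008294,2.19898423248038,-0.442714683857946,0.840857395364981
-0.145653410753185,0.288068699897436,-0.176936339265109,0.873264620906623,0.250503898594814,-0.651443583852051,2.41226833155544,-0.775357177065009,-0.209916341392341,0.139623505130949,-0.451193392626062,0.806352347403468,-1.35799623045605,-1.66432595705302,0.0893084796751078,-0.242983052482991
1.82113044481145,-0.134996440233924,2.03788937445083,1.51545461918387,1.37841279598195,0.322571315467103,0.962961191208786,0.272485787555801,-0.0982900680161311,0.328914719646277,1.2553555060465,1.15887824820304,2.0019532061301,0.970905371621628,-0.0334582458729166,0.778373957918193
-0.313720205824794,1.43168363488605,-0.00724018261438433,2.25914808912143,-0.295349459726644,-1.54152513660305,-1.0925258324595,0.503962086757859,0.566002718847925,0.908330953568325,-0.514013709942388,-0.248815219449575,0.229218737167339,1.5641952134796,2.7584160482618,0.418069400756589
0.638236892812659,-0.451005063481188,0.763817548100492,1.73495145103068,0.944337749984431,-0.0173801179503167,-0.6707814369676,-0.194071843901766,-0.419103829461117,-0.120400487492925,-2.04951382399287,0.327892751951156,1.3530532020573,-0.107070330529929,-0.339853304592328,-0.672214404119072
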