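0.918919013234159,-1.67451954019203,-0.910378739448541,-0.695170413414382,1.53766387036988,1.3224260964431,-0.205199584704585,1.25694501391514,0.387269885282661,1.48927413697156,0.735872234932301,-0.0813776841258095,-0.887292492963101,0.0347317850680509,-2.28537326278533,0.447118383680644
0.822867024967595,-0.256403645610768,-0.415856169323876,0.0974421565507218,-0.704187788931173,0.0285201285611961,1.21061118778095,-0.249300797167045,0.256357516960088,-0.613587045204726,-1.5139234858914,2.07774747777159,-0.281420485801375,-0.841445208444171,-0.61804469095354,1.00874248871441
0.515128041658587,0.17063324299465,1.80133873476685,-1.72386046981223,-0.587140815538429,-0.568649242924539,-1.15548033578544,-0.986535422606097,0.171669821721445,0.853577419905353,1.77628770099379,-1.43837037389062,0.38996784827952,0.620138845815809,0.031055852327876,-1.21737962983893
0.648271189547863,-0.275922974769427,0.0163846326158182,-0.669626224461508,0.287561796154364,-0.229311194239546,0.0361388007640364,1.05941902373668,0.560088035465461,-0.0839214287591068,0.103024873403372,-0.195982880278148,0.104258754078084,-0.454856223459562,-0.283220695369427,0.156078961608251
-0.433851604675431,1.64173743531717,-1.092316980169,0.568564647274934,1.87199350020644,0.564696572859431,0.908758368359605,-0.0598053410298321,0.606800463037586,-1.97298676310139,-0.502717458509008,0.339205585858931,1.81760232627487,1.01308385979464,1.32189202120266,-0.184547074046348
1.71132858867117,0.0330864284826951,0.623307328880723,0.893286897654977,0.15741098787655,2.1678705777218,0.424642595368715,0.402204079614116,0.365313408752648,-0.123268500576308,-1.38797976176952,0.952495572574811,1.0959125776694,-1.15703579645996,0.175957552230138,1.10955584479616
-1.69189266837656,0.252535762579671,-0.175492460982278,0.811726613968841,-0.688219616216335,0.641872414149095,1.48995041358308,0.802891778083989,-0.738758993198859,0.819330349913296,-0.287951149728825,0.0726976684347268,-1.58055049876626,-0.553354506098688,0.155332936602563,0.141258021030093
-0.742204000159332,0.815631806349517,0.339273338495743,-0.243716699882624,0.329905331274461,0.327128434681729,-0.574504947365006,1.7447355170887,0.821185019431951,0.574863608316837,-0.284328478422636,0.536796472534177,-1.22148059054793,-0.343084152416964,1.22976857000102,1.1063466931774
-0.102730433489598,-0.619805521103438,-1.14547956476413,0.994573511165827,-1.05554195501955,1.42760164354561,0.11423998508553,-0.910144475506529,0.334465085291544,-1.15670735066716,0.625723871729508,-0.215185012649389,0.611438368632549,-0.793224663729256,1.68813270301512,-0.970676119209753
1.67165739895048,0.274186104699292,-0.973741595019619,-0.168190666149831,-0.531572475111446,-0.38846700057412,0.416276679837751,-1.11761304619554,-0.375671641311332,-1.02312897996001,-1.27931921638659,-0.0576599518045607,-1.50732831313892,-0.0266821306187742,-0.653306019614809,0.536493938252546
0.91419942496296,1.46780499710861,-1.23588168684182,-0.682602888798586,0.900607418004704,-0.678841047513058,-0.0204983805182674,0.23677240013138,-1.33687944705862,0.245847307184688,-0.0455884199377495,1.35337762190886,0.225963448532313,0.925305590515221,-0.776872204681384,0.286124864729101
1.44936152646409,-0.334652858489264,-0.854638116267916,0.146468037632865,1.1901391872449,-1.71360024846789,-0.929277529028857,-2.01579840280536,0.684673094311014,0.828392951785421,1.1555462041812,0.399449387977882,1.77318983237006,0.613085538881755,-0.335652120504438,0.00299086184923545
-0.111176467870759,-2.25552923489515,1.26529424068936,0.950514681467119,1.51944528807267,-1.87510484623105,-0.419793445421684,-0.36930192722262,-0.813318469394373,0.980479333280069,-0.595587113221127,-0.499729123097007,0.902303598928311,0.513194233154629,0.253153583642377,-0.17373625868149
-0.459540799405656,1.25027998282928,-1.57267856683819,-0.821197244731784,0.480555334623191,0.483769849202491,0.771382862700196,-2.54063908109686,0.572789797979497,0.12802525468445,-0.246846650017343,0.600017870529597,-2.59982408052182,-0.483779428985677,0.242619137630312,0.916830675825151
-0.47107707210197,0.309635327998978,0.516346329144699,0.245355604502073,1.04835759893681,-0.490428778963041,-0.0111227120203127,-1.34204739159895,0.0141685707945739,0.834783371192217,-0.594350519840908,0.859910661885119,-0.616820574820572,1.27114532068294,-0.148657765720095,0.0788713260235907
0.202776217577322,0.974896944827605,-1.14174962678419,-0.131912530926701,-0.92734412652527,0.783318436878138,0.59096854518543,0.878711629233639,0.5079646046082,1.31707066287821,-0.865582759138845,-0.195862322827132,-0.580542840591428,-1.49404969356021,-0.465894935853074,-1.2157284497523
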