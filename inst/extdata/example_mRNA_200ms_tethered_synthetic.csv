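TRACK_ID,FRAME,POSITION_X,POSITION_Y,POSITION_T
1,0,0.391342277241667,-0.240894274720691,0
1,1,0.445195375400858,-0.183603058347037,0.2
1,2,0.438597686715867,-0.236183055519952,0.4
1,3,0.424673502697182,-0.220053135390151,0.6
1,4,0.465063029107942,-0.297854822030205,0.8
1,5,0.409877604175316,-0.254549874692999,1
1,6,0.479149544048368,-0.225783781250234,1.2
1,7,0.401245517296255,-0.230639786573992,1.4
1,8,0.483344604155963,-0.237423896301072,1.6
1,9,0.564951783687142,-0.134327483112357,1.8
1,10,0.441672607417356,-0.130979564078175,2
1,11,0.481541238829143,-0.0824044606312733,2.2
1,12,0.474759383551448,-0.151080484066938,2.4
1,13,0.444942616873355,-0.128684633148345,2.6
1,14,0.481233762492598,-0.249438229616482,2.8
1,15,0.491897847264422,-0.269937308843996,3
1,16,0.433792051196892,-0.189053822507987,3.2
1,17,0.47044350492966,-0.0880038497197417,3.4
1,18,0.386543067566989,-0.172723905932359,3.6
1,19,0.408558040406333,-0.0802608065730599,3.8
1,20,0.365837978835009,-0.115102017189485,4
2,0,-0.0646287566238127,0.209442031634635,0
2,1,-0.146142270303755,0.13296650498865,0.2
2,2,-0.210544398889658,0.145325782868259,0.4
2,3,-0.161132583336147,0.054134159717465,0.6
2,4,-0.136847362408051,0.0395682017573673,0.8
2,5,-0.0421519964393986,0.00528932032061836,1
2,6,-0.120955147164964,-0.001844746521309,1.2
2,7,-0.0311724550382534,0.0487136721964946,1.4
2,8,-0.0198961311900559,-0.0309325184716714,1.6
2,9,0.0566823224024888,-0.0851147718834354,1.8
2,10,-0.0422492101212452,-0.164941396954671,2
2,11,0.0458573220670165,0.00916482811397553,2.2
2,12,0.00617678848536424,-0.0417831712027831,2.4
2,13,0.0193833371939029,-0.0168656727650307,2.6
2,14,-0.00476007549758105,-0.0837015178945666,2.8
2,15,-0.0332414614407318,-0.0236811909915054,3
2,16,0.0842498387960665,-0.0228968610491368,3.2
2,17,0.0435237812133875,-0.0353136918200797,3.4
2,18,0.109730103274414,-0.0793666087743956,3.6
2,19,0.0489181818647641,0.00978153853854523,3.8
2,20,-0.043761787171204,-0.0156186018445322,4
3,0,-0.0957031752126217,0.495246284707926,0
3,1,-0.240390560353271,0.437088994908852,0.2
3,2,-0.201437391293156,0.407756948673231,0.4
3,3,-0.160011299345226,0.384831632747338,0.6
3,4,-0.157864284369774,0.378489658206926,0.8
3,5,-0.117314814068805,0.448464913195819,1
3,6,-0.156904284495392,0.420322559227433,1.2
3,7,-0.00751454646508942,0.356070108638095,1.4
3,8,-0.012684561200875,0.348740176300361,1.6
3,9,0.0686746293626979,0.263054308099416,1.8
3,10,0.102501186361816,0.363149505323019,2
3,11,0.0148264249175467,0.363184085852033,2.2
3,12,-0.0492983867047188,0.389650109478034,2.4
3,13,-0.084714311736133,0.325079513532979,2.6
3,14,-0.0596804993701917,0.355210346639304,2.8
3,15,-0.0045435290986078,0.302977959938054,3
3,16,-0.0243278465818119,0.381513540867748,3.2
3,17,0.0265910960957593,0.420506796151921,3.4
3,18,0.0118306076144677,0.31293835022988,3.6
3,19,-0.00187620570698766,0.293362615022927,3.8
3,20,-0.037708940961299,0.268414366086786,4
4,0,-0.161573362417954,-0.130515237541218,0
4,1,-0.146855169715916,-0.132501879175344,0.2
4,2,-0.178538477902143,-0.154502184844948,0.4
4,3,-0.132168469092917,-0.143077178074447,0.6
4,4,-0.155176994533165,-0.196109846989851,0.8
4,5,-0.144169291649892,-0.326342068988685,1
4,6,-0.182001799382982,-0.288759433843611,1.2
4,7,-0.326191797144714,-0.387029472254552,1.4
4,8,-0.235019873629784,-0.355653499991587,1.6
4,9,-0.234655370157223,-0.314297438125128,1.8
4,10,-0.24724040082692,-0.392102579911148,2
4,11,-0.279864169553949,-0.381889414450353,2.2
4,12,-0.210002187894971,-0.484537072710824,2.4
4,13,-0.263717052546207,-0.455223548947641,2.6
4,14,-0.292186431989253,-0.482310187304534,2.8
4,15,-0.304986132683812,-0.393889308229974,3
4,16,-0.327746141208439,-0.416740574588247,3.2
4,17,-0.250437763744081,-0.346512472970081,3.4
4,18,-0.344190402321726,-0.413377699737262,3.6
4,19,-0.268643552557947,-0.198474243854484,3.8
4,20,-0.227883812724593,-0.184358996225216,4
5,0,-0.324642313409936,0.344316504800608,0
5,1,-0.295339803037834,0.481203694389713,0.2
5,2,-0.305222792007,0.457135313247096,0.4
5,3,-0.286795136094512,0.500168506816223,0.6
5,4,-0.219548079487144,0.399454652855289,0.8
5,5,-0.241825768770401,0.479094848332342,1
5,6,-0.378056390475186,0.524008878432502,1.2
5,7,-0.407443419999515,0.367513504529866,1.4
5,8,-0.408799549963831,0.48646943842613,1.6
5,9,-0.430199944516555,0.529635981469132,1.8
5,10,-0.423532102488293,0.440997116467749,2
5,11,-0.369448525632982,0.391138013920497,2.2
5,12,-0.44637160928192,0.363699914362819,2.4
5,13,-0.391809362679895,0.407026385836281,2.6
5,14,-0.494079864933843,0.408288811036577,2.8
5,15,-0.448718934585798,0.433615581814613,3
5,16,-0.45214152680195,0.476265821118902,3.2
5,17,-0.476384504898101,0.424165013413844,3.4
5,18,-0.50229316753762,0.504969563296163,3.6
5,19,-0.479056276249864,0.421058372373955,3.8
5,20,-0.408030919808631,0.503643935187544,4
6,0,0.461678825081793,-0.488844667640961,0
6,1,0.364374153409712,-0.457299706835211,0.2
6,2,0.376085458023821,-0.425492047802396,0.4
6,3,0.299627194138261,-0.463106706174351,0.6
6,4,0.368366222899094,-0.366710012492736,0.8
6,5,0.293161884994931,-0.334407858844708,1
6,6,0.347985858131603,-0.44880762941708,1.2
6,7,0.186321883554195,-0.448244823299789,1.4
6,8,0.284979771020857,-0.457424299518038,1.6
6,9,0.191684943015619,-0.39577518912314,1.8
6,10,0.259257503663695,-0.517170312651819,2
6,11,0.237877676581077,-0.459508723608662,2.2
6,12,0.206644920137676,-0.431474681160809,2.4
6,13,0.194675276060427,-0.435379220998448,2.6
6,14,0.288502250443619,-0.423628339499815,2.8
6,15,0.319721422070893,-0.392204721525838,3
6,16,0.352326104079705,-0.39172007364014,3.2
6,17,0.318136221071565,-0.322703952969894,3.4
6,18,0.414065133719251,-0.242520429304917,3.6
6,19,0.406474260791567,-0.296731385203357,3.8
6,20,0.394346474223461,-0.2869057590994,4
7,0,-0.224585521723565,-0.328643029416488,0
7,1,-0.16502734396681,-0.324928877211961,0.2
7,2,-0.096843261239172,-0.286661771770248,0.4
7,3,-0.183532370575667,-0.236192915158903,0.6
7,4,-0.246095869155276,-0.132007238996109,0.8
7,5,-0.195822043135246,-0.21896193175364,1
7,6,-0.148707387243178,-0.22312723568648,1.2
7,7,-0.219835278963441,-0.0930411386054382,1.4
7,8,-0.313195532211337,-0.167350106723832,1.6
7,9,-0.269800326303002,-0.187063602492133,1.8
7,10,-0.338263905415561,-0.2366343193169,2
7,11,-0.338621005433138,-0.240540444858131,2.2
7,12,-0.399529924972738,-0.119555182799577,2.4
7,13,-0.371541060950154,-0.160427630509884,2.6
7,14,-0.25149195584657,-0.10260354517117,2.8
7,15,-0.18204123680628,-0.168530192183818,3
7,16,-0.197244582852698,-0.158647220349253,3.2
7,17,-0.200401617032153,-0.141667716568946,3.4
7,18,-0.17515112212758,-0.214811079596214,3.6
7,19,-0.184719797386587,-0.169512231010268,3.8
7,20,-0.276765378711327,-0.294437893837221,4
8,0,0.149407841109136,-0.256644907618058,0
8,1,0.0967056039330792,-0.21235965184101,0.2
8,2,0.193597709229601,-0.132536479919691,0.4
8,3,0.224525547672652,-0.0951563540092726,0.6
8,4,0.198679844209316,-0.199468289595145,0.8
8,5,0.321384063211912,-0.184349974011536,1
8,6,0.349216655575558,-0.0877127274274306,1.2
8,7,0.356934271635922,-0.163338598143785,1.4
8,8,0.387860572051521,-0.0726806067501871,1.6
8,9,0.426160351416065,-0.0361140349088819,1.8
8,10,0.38677731672485,-0.0311341874978336,2
8,11,0.35449976987711,-0.0496736138970104,2.2
8,12,0.274546080042084,0.00748893460185829,2.4
8,13,0.251477355723673,-0.0193673010159217,2.6
8,14,0.176844118541215,0.0438015199480199,2.8
8,15,0.241351427496025,0.0164252157666068,3
8,16,0.220429992669425,0.0477879573444837,3.2
8,17,0.192311642342471,0.0323711236565356,3.4
8,18,0.220047312857813,-0.0273226955371628,3.6
8,19,0.200409193144035,-0.00136900106475259,3.8
8,20,0.201727532888377,0.113821145149854,4
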