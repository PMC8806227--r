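gene	B_cells	T_cells_CD4	T_cells_CD8	NK_cells	Macrophages	Monocytes
RG001	9.361151700373739	0.7080465470673516	0.42104979942087084	0.9262507755309344	0.16087313718162477	0.5353913274360821
RG002	0.9433678719680756	6.544415788259357	0.46957161324098706	0.876366799348034	0.6052941608708352	0.5001125750830397
RG003	0.3575255813077093	0.7835898407967761	9.487186539452523	0.3852777140215039	0.1636497048428282	0.15434703095816077
RG004	0.8474028634605929	0.6098395816748962	0.6307104732142761	11.16726417420432	0.29025274496525527	0.39475541985593743
RG005	0.6775709670037031	0.8647207467118279	0.7476915631210431	0.7680398067459464	6.136200067587197	0.8905861425679177
RG006	0.5671863542171195	0.2705265418626368	0.4554757406935096	0.7726250051287934	0.5337833035271615	6.749374962877482
RG007	9.91506072320044	0.34415795323438947	0.9272835362236946	0.926113630621694	0.2435228690970689	0.452960611297749
RG008	0.22119993751402944	7.932203424163163	0.9663132642162964	0.8138720882823691	0.2346210955642164	0.24296209735330196
RG009	0.6912930613616481	0.7238843383500353	8.820554251782596	0.2199966564308852	0.5493455923395232	0.38795284095685934
RG010	0.7345583056332543	0.316490265680477	0.752047839993611	9.148743612226099	0.9465083902468905	0.37626905823126433
RG011	0.5119675986235962	0.13868991641793402	0.91327107262332	0.27520852943416685	9.07943716691807	0.19703012900426986
RG012	0.7472010264871642	0.2264311847044155	0.6431266762781889	0.8056984443916008	0.2695908966241405	9.48932533012703
RG013	7.677440992556512	0.29474687355104834	0.6683565690182149	0.21598494555801154	0.3427445604698732	0.5472130852984265
RG014	0.3298859419068322	10.549620675388724	0.9436472646892071	0.216180355171673	0.5776696702931077	0.18376720473170283
RG015	0.5160635402891786	0.27766930805519224	8.190084720030427	0.16502780015580357	0.11930520567111672	0.2905962923541665
RG016	0.9460130704799667	0.7474202539073304	0.6218388091539964	9.940865251701325	0.8188842767383904	0.937450671615079
RG017	0.9804037855472416	0.10709626486059279	0.8392635315191	0.5786869927775115	9.784356909804046	0.3671617660904304
RG018	0.20573862548917532	0.4379409681539983	0.20234674818348142	0.20107741749379784	0.5858184572309256	7.440897648688406
RG019	11.879445536993444	0.5629669374786318	0.7880569827975705	0.7688689477508888	0.6141105077229441	0.910963430115953
RG020	0.6042994716204703	6.626477577723563	0.6612521114759147	0.7581839295569808	0.6570563922636211	0.9917162139201536
RG021	0.913628248567693	0.6234436022583395	7.68074776371941	0.8966059183469042	0.7433683241484687	0.4872998991981149
RG022	0.22483915095217527	0.24211468736175448	0.17223801992367954	7.377116236835718	0.2109705208102241	0.4543992300285027
RG023	0.9900025560287758	0.4231254752725363	0.5176625961903483	0.8667378864949569	8.512629745993763	0.2277180059114471
RG024	0.9520014093024656	0.6810686905635521	0.8014313453109935	0.4985166414408013	0.9511652463581413	10.331327331718057
RG025	9.863184648100287	0.7982410263735801	0.7601751636015252	0.24209209037944676	0.5500225831521676	0.608340000314638
RG026	0.562790605914779	10.261667115613818	0.8355073999613524	0.4980921749491245	0.2217074491782114	0.9416255548829213
RG027	0.45118312039412556	0.3103330587502569	9.598295129835606	0.9709603005088866	0.8823320384835824	0.4225601305719465
RG028	0.9151643178192899	0.18098246471490712	0.9502482929732651	10.327356188558042	0.2845446508843452	0.8578064628178254
RG029	0.5022726652910933	0.17705085843335838	0.36426145723089576	0.327212595497258	11.275595671031624	0.7501682929228991
RG030	0.8524038339965045	0.37469653252046553	0.2341648472007364	0.33372098216786983	0.8980782384052872	6.875572144053876
RG031	9.49547061463818	0.700683863204904	0.7474407321540639	0.587814346794039	0.22266624271869662	0.931589606963098
RG032	0.8299496271414682	11.79886430175975	0.39167735723312946	0.684888253849931	0.8068144979421049	0.10214029613416642
RG033	0.44929745453409853	0.2877129612490535	10.911417677532881	0.40277721907477826	0.5079730727477	0.24438692345283927
RG034	0.7166527564637363	0.9397307146107778	0.4549969016341493	8.944502369966358	0.222168177459389	0.45934565616771583
RG035	0.10355350491590798	0.9330802737502382	0.7107335811248049	0.5061797651927918	6.647922438103706	0.7077876196010038
RG036	0.8496244722278788	0.7606848709052428	0.7982425384689122	0.8548795301001519	0.40304218612145637	6.9170326218008995
RG037	9.695226155687124	0.39976478507742286	0.26908213961869476	0.6171736008953304	0.38734670362900947	0.5804459026781842
RG038	0.28689307554159316	7.2089473572559655	0.12617723701987416	0.4180153396679088	0.46340453326702125	0.38525514155626295
RG039	0.9159412670182064	0.7695771816885099	6.586993682663888	0.5926834704121575	0.531169576337561	0.833281831163913
RG040	0.6506007791031152	0.6572433160385117	0.7121477603213862	11.791533554904163	0.43111163820140064	0.3629975691204891
RG041	0.4416033164830878	0.6636208100710064	0.9413406583946198	0.5409915135242045	11.881672178395092	0.46821888219565155
RG042	0.49219442647881806	0.2954419284127653	0.5954446759307758	0.2544689018512145	0.1449029376031831	7.555336021352559
RG043	11.550841766875237	0.294910579873249	0.6415896118851379	0.5887278946116566	0.2686210404383019	0.8187369742197916
RG044	0.9761859223945066	6.650931926909834	0.27729503931477667	0.9653209262993186	0.9843934723408893	0.4238067247206345
RG045	0.4885761240031571	0.948210122785531	11.78213715646416	0.382315439847298	0.3954466626280919	0.1364388190675527
RG046	0.9618189369793981	0.9663472123909742	0.26160016534850006	11.441654882859439	0.25389675146434454	0.13697770587168634
RG047	0.8989794149529189	0.7658697512932122	0.50669784497004	0.37634896039962773	7.589799787849188	0.9589908145368099
RG048	0.6759808925213292	0.7599213151494041	0.3853480166057125	0.2669082230422646	0.11681867050938309	10.667317560408264
RG049	8.34013737179339	0.5821851609973238	0.20455720336176456	0.14351209907326848	0.4055365753360093	0.8257777007995173
RG050	0.6569543865974993	6.332413072697818	0.267491941084154	0.3211067325435579	0.12669703802093865	0.9190531080821529
RG051	0.4000844901427627	0.6480437072925269	7.012418660335243	0.4159962299279869	0.8805057967547327	0.49606859157793226
RG052	0.41207342338748276	0.8531214034883305	0.4706848640926182	9.307503167074174	0.7585368397412822	0.6187028527259827
RG053	0.4586368702817708	0.7763703064294531	0.4726447135675699	0.37368819711264223	6.505665139295161	0.16630101564805955
RG054	0.8062234981218352	0.5074584153015167	0.532279116101563	0.11579349229577929	0.4478086106013507	8.558797798119485
RG055	7.727518110070378	0.5822109944419935	0.4847450190456585	0.9968974112998694	0.39920139147434386	0.7659016982885077
RG056	0.7739158475538715	10.978341090492904	0.22284132412169128	0.8239539813948795	0.18080017403699458	0.5281399114523083
RG057	0.709549147170037	0.10124275921843946	6.516500435303897	0.1779225415783003	0.78135004225187	0.716968857939355
RG058	0.25413789735175674	0.42009935844689605	0.6330738182878122	6.453594597056508	0.6426716474816203	0.9563634485239163
RG059	0.33497916744090617	0.6509197811363265	0.8149572798749432	0.5991272770334035	8.315443054307252	0.5477180388057604
RG060	0.562971641193144	0.8460479174973443	0.7921291831415147	0.47924057964701205	0.12926573511213066	6.360290016978979
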