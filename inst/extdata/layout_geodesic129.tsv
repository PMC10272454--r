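label	x	y	z
E1	-0.146094785933916	0.133834791343192	0.98017578125
E2	0.0210688151747047	-0.240068282079711	0.97052734375
E3	0.168518593665795	0.2198026640255	0.96087890625
E4	-0.303765509133416	-0.0537318414217456	0.95123046875
E5	0.284163052430875	-0.180761273674124	0.94158203125
E6	-0.0941400441842156	0.350196271997867	0.93193359375
E7	-0.178145239983393	-0.343007819199756	0.92228515625
E8	0.383967867629996	0.140224449426294	0.91263671875
E9	-0.397159096555484	0.163941501604697	0.90298828125
E10	0.190468639109427	-0.407020418510581	0.89333984375
E11	0.140085789996995	0.4466155729045	0.88369140625
E12	-0.420361678698392	-0.243608185126356	0.87404296875
E13	0.49108642313029	-0.107963972519496	0.86439453125
E14	-0.29851883195363	0.424612319873266	0.85474609375
E15	-0.0687033521901688	-0.530179027120642	0.84509765625
E16	0.420226352177923	0.35416721449797	0.83544921875
E17	-0.563480346888943	0.0233016814158628	0.82580078125
E18	0.409587710912453	-0.407594478447487	0.81615234375
E19	-0.027309711405633	0.590597687826859	0.80650390625
E20	-0.387097229808569	-0.463871853638211	0.79685546875
E21	0.611181418028453	0.0822335953688715	0.78720703125
E22	-0.516164333709143	0.359133699187529	0.77755859375
E23	0.140590451078881	-0.624938650583829	0.76791015625
E24	0.324137209990799	0.565662651213315	0.75826171875
E25	-0.631641888948548	-0.201510990423893	0.74861328125
E26	0.611618817490758	-0.282583406789472	0.73896484375
E27	-0.264133947213025	0.631134563705912	0.72931640625
E28	-0.23499363886738	-0.653342180214255	0.71966796875
E29	0.623334453400044	0.327607119043526	0.71001953125
E30	-0.69020279542986	0.18193524183136	0.70037109375
E31	0.391090464849759	-0.608235530404583	0.69072265625
E32	0.124019670325138	0.721634969999737	0.68107421875
E33	-0.585908543386666	-0.453760508483653	0.67142578125
E34	0.747140717033073	-0.0618990811765398	0.66177734375
E35	-0.514815552348479	0.556500527127611	0.65212890625
E36	0.00373823383996349	-0.766292941950099	0.64248046875
E37	0.520233365480889	0.573481355986772	0.63283203125
E38	-0.778738226610877	-0.0721732838090461	0.62318359375
E39	0.62901702806021	-0.477401498170659	0.61353515625
E40	-0.142662472219119	0.784199113706262	0.60388671875
E41	-0.428368843617902	-0.680720940558249	0.59423828125
E42	0.782475819158092	0.214444181588643	0.58458984375
E43	-0.72793651475345	0.373565000860455	0.57494140625
E44	0.286745710799558	-0.773447320003029	0.56529296875
E45	0.313480789915178	0.770057757084573	0.55564453125
E46	-0.757071781176	-0.358790445464675	0.54599609375
E47	0.80653444434617	-0.248663189311056	0.53634765625
E48	-0.429805154526707	0.733386298011091	0.52669921875
E49	-0.179709730629817	-0.836876874053599	0.51705078125
E50	0.702505942914003	0.499027315612597	0.50740234375
E51	-0.86066010934011	0.107262411885695	0.49775390625
E52	0.56571237887327	-0.664622115014155	0.48810546875
E53	0.0320011939274323	0.877527659298928	0.47845703125
E54	-0.620000200977218	-0.629140885028431	0.46880859375
E55	0.887194545985652	0.0453628535895627	0.45916015625
E56	-0.68862535868605	0.568976563736091	0.44951171875
E57	0.124094687960483	-0.889449718774464	0.43986328125
E58	0.511954883789483	0.743516903090481	0.43021484375
E59	-0.884157785685591	-0.203442640430938	0.42056640625
E60	0.793211427509496	-0.449401884983499	0.41091796875
E61	-0.282645902634741	0.871260039835523	0.40126953125
E62	-0.381842483362736	-0.837155443647972	0.39162109375
E63	0.850774767400552	0.360942079885202	0.38197265625
E64	-0.874851372864396	0.309854403760031	0.37232421875
E65	0.437574738540962	-0.822796831475128	0.36267578125
E66	0.234062314286543	0.905862311610129	0.35302734375
E67	-0.787496533965181	-0.511800875082664	0.34337890625
E68	0.929816208429141	-0.155131533771701	0.33373046875
E69	-0.582898235578351	0.74511776517576	0.32408203125
E70	-0.073761371471766	-0.946409412041144	0.31443359375
E71	0.695975458011141	0.650172415883546	0.30478515625
E72	-0.955409556463489	-0.00932183800125702	0.29513671875
E73	0.712963675209816	-0.640452370672662	0.28548828125
E74	-0.0933719385977691	0.95665775577396	0.27583984375
E75	-0.578995228378621	-0.770653398586833	0.26619140625
E76	0.950070087936339	0.177630327347481	0.25654296875
E77	-0.822670147215809	0.512110260899702	0.24689453125
E78	0.261333429588694	-0.935638354055549	0.23724609375
E79	0.44035817856323	0.868495239734785	0.22759765625
E80	-0.91343010644653	-0.343720204066251	0.21794921875
E81	0.907667811955398	-0.364348634786437	0.20830078125
E82	-0.424039606783011	0.883587945935175	0.19865234375
E83	-0.284734228114557	-0.939789307644138	0.18900390625
E84	0.846328095802564	0.501557942898599	0.17935546875
E85	-0.964527358363745	0.202204101125986	0.16970703125
E86	0.575566037051253	-0.801938266676362	0.16005859375
E87	0.117477197389953	0.981619016212631	0.15041015625
E88	-0.75077483340695	-0.645386154218785	0.14076171875
E89	0.990873309448439	-0.0312952408930719	0.13111328125
E90	-0.710378605616021	0.693259351480978	0.12146484375
E91	0.0555844950379655	-0.992173097400201	0.11181640625
E92	0.629874446766174	0.769947977120861	0.10216796875
E93	-0.985476207702294	-0.14239656031655	0.0925195312500001
E94	0.823548921302746	-0.561159118291561	0.0828710937500001
E95	-0.228374771860269	0.970815845662536	0.0732226562500001
E96	-0.487703499295476	-0.870691458259052	0.0635742187500001
E97	0.94830027244332	0.31275965756552	0.05392578125
E98	-0.91094573510821	0.410143126869886	0.04427734375
E99	0.394805829533229	-0.918111755625919	0.03462890625
E100	0.329152775148937	0.943946199098648	0.02498046875
E101	-0.880504802580734	-0.473789216266065	0.01533203125
E102	0.969395144823206	-0.245439911088804	0.00568359375000005
E103	-0.549014084897844	0.835803693816808	-0.00396484374999995
E104	-0.15973783543108	-0.987065601925932	-0.0136132812499999
E105	0.78439934007112	0.619819786499904	-0.0232617187499998
E106	-0.996803535899248	0.0727985743978367	-0.0329101562499999
E107	0.685587160121547	-0.726745493260533	-0.0425585937499998
E108	-0.0146144099914102	0.998529341035437	-0.0522070312499999
E109	-0.663354347498743	-0.745744534435375	-0.0618554687499998
E110	0.992238611257865	0.10173362138474	-0.0715039062499999
E111	-0.799773269644571	0.594791572120784	-0.0811523437499998
E112	0.187794971694492	-0.978002181352708	-0.0908007812499999
E113	0.521670824005536	0.847212786632674	-0.10044921875
E114	-0.955965437988273	-0.27204519378248	-0.11009765625
E115	0.887665035157514	-0.444647791392722	-0.11974609375
E116	-0.353749153463528	0.926346906782999	-0.12939453125
E117	-0.364413825809278	-0.920798358165474	-0.13904296875
E118	0.889436128501092	0.432196990994138	-0.14869140625
E119	-0.946350714982122	0.281689222608982	-0.15833984375
E120	0.506711023804678	-0.845590844154243	-0.16798828125
E121	0.197216213953909	0.964132232168088	-0.17763671875
E122	-0.795233515305396	-0.576652344470596	-0.18728515625
E123	0.974027057161662	-0.111751740790481	-0.19693359375
E124	-0.641427050775016	0.738847212147876	-0.20658203125
E125	-0.0260600724765367	-0.975994496401836	-0.21623046875
E126	0.676970907909976	0.700492048173887	-0.22587890625
E127	-0.970069426380689	-0.0590946558286849	-0.23552734375
E128	0.753360369001528	-0.61019422375694	-0.24517578125
Cz	0	0	1
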