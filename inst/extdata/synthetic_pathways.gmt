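PLANTED_PATHWAY	synthetic planted set	G001	G002	G003	G004	G005	G006	G007	G008	G009	G010	G011	G012	G013	G014	G015	G016	G017	G018	G019	G020	G021	G022	G023	G024	G025	G026	G027	G028	G029	G030
BACKGROUND_PATHWAY_1	synthetic background set	G043	G084	G113	G062	G090	G059	G111	G138	G151	G115	G156	G142	G102	G195	G031	G171	G163	G085	G174	G073
BACKGROUND_PATHWAY_2	synthetic background set	G072	G200	G127	G187	G055	G145	G062	G111	G044	G141	G036	G073	G143	G188	G061	G124	G190	G068	G125	G184
BACKGROUND_PATHWAY_3	synthetic background set	G114	G045	G064	G042	G158	G184	G071	G096	G086	G182	G128	G055	G122	G137	G091	G044	G154	G125	G062	G168
BACKGROUND_PATHWAY_4	synthetic background set	G058	G148	G067	G168	G143	G035	G065	G108	G044	G186	G152	G127	G157	G061	G073	G111	G057	G060	G130	G105
BACKGROUND_PATHWAY_5	synthetic background set	G175	G092	G043	G156	G154	G093	G079	G091	G146	G031	G200	G058	G032	G166	G157	G033	G198	G042	G081	G125
BACKGROUND_PATHWAY_6	synthetic background set	G195	G077	G086	G174	G040	G183	G033	G112	G058	G123	G087	G114	G148	G091	G132	G180	G184	G084	G085	G200
BACKGROUND_PATHWAY_7	synthetic background set	G088	G195	G073	G115	G192	G183	G132	G172	G079	G169	G186	G048	G085	G066	G178	G101	G143	G057	G124	G163
BACKGROUND_PATHWAY_8	synthetic background set	G116	G178	G144	G169	G068	G136	G157	G181	G120	G145	G135	G041	G177	G066	G089	G143	G060	G138	G179	G077
BACKGROUND_PATHWAY_9	synthetic background set	G135	G118	G144	G165	G172	G042	G081	G040	G151	G119	G067	G057	G076	G061	G121	G130	G150	G083	G054	G178
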