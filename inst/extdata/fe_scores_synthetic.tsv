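protein	pe	fe
candidate_001	1	1
candidate_002	1	5
candidate_003	1	3
candidate_004	1	1
candidate_005	1	1
candidate_006	1	3
candidate_007	1	1
candidate_008	1	1
candidate_009	1	5
candidate_010	1	4
candidate_011	1	4
candidate_012	1	5
candidate_013	1	2
candidate_014	1	1
candidate_015	1	3
candidate_016	1	3
candidate_017	1	5
candidate_018	1	2
candidate_019	1	5
candidate_020	1	5
candidate_021	1	5
candidate_022	1	2
candidate_023	1	4
candidate_024	1	5
candidate_025	1	3
candidate_026	1	4
candidate_027	1	5
candidate_028	1	1
candidate_029	1	5
candidate_030	1	1
candidate_031	1	5
candidate_032	1	3
candidate_033	1	1
candidate_034	1	4
candidate_035	1	3
candidate_036	1	5
candidate_037	1	5
candidate_038	1	2
candidate_039	1	5
candidate_040	1	4
candidate_041	1	5
candidate_042	1	5
candidate_043	1	1
candidate_044	1	5
candidate_045	1	5
candidate_046	1	2
candidate_047	1	5
candidate_048	1	3
candidate_049	1	4
candidate_050	1	2
candidate_051	1	5
candidate_052	1	1
candidate_053	1	2
candidate_054	1	5
candidate_055	1	1
candidate_056	1	1
candidate_057	1	1
candidate_058	1	5
candidate_059	1	2
candidate_060	1	3
candidate_061	1	3
candidate_062	1	5
candidate_063	1	1
candidate_064	1	2
candidate_065	1	3
candidate_066	1	1
candidate_067	1	1
candidate_068	1	1
candidate_069	1	5
candidate_070	1	5
candidate_071	1	2
candidate_072	1	5
candidate_073	1	3
candidate_074	1	2
candidate_075	1	5
candidate_076	1	1
candidate_077	1	5
candidate_078	1	1
candidate_079	1	5
candidate_080	1	5
candidate_081	1	5
candidate_082	1	2
candidate_083	1	2
candidate_084	1	1
candidate_085	1	1
candidate_086	1	5
candidate_087	1	2
candidate_088	1	1
candidate_089	1	5
candidate_090	1	1
candidate_091	1	1
candidate_092	1	4
candidate_093	1	2
candidate_094	1	5
candidate_095	1	2
candidate_096	1	1
candidate_097	1	1
candidate_098	1	5
candidate_099	1	3
candidate_100	1	4
candidate_101	1	5
candidate_102	1	1
candidate_103	1	5
candidate_104	1	1
candidate_105	1	5
candidate_106	1	3
candidate_107	1	5
candidate_108	1	5
candidate_109	1	5
candidate_110	1	1
candidate_111	1	5
candidate_112	1	2
candidate_113	1	1
candidate_114	1	3
candidate_115	1	1
candidate_116	1	2
candidate_117	1	2
candidate_118	1	2
candidate_119	1	1
candidate_120	1	4
candidate_121	1	5
candidate_122	1	1
candidate_123	1	4
candidate_124	1	5
candidate_125	1	2
candidate_126	1	2
candidate_127	1	1
candidate_128	1	1
candidate_129	1	1
candidate_130	1	5
candidate_131	1	3
candidate_132	1	2
candidate_133	1	2
candidate_134	1	4
candidate_135	1	3
candidate_136	1	3
candidate_137	1	4
candidate_138	1	1
candidate_139	1	1
candidate_140	1	1
candidate_141	1	5
candidate_142	1	1
candidate_143	1	4
candidate_144	1	1
candidate_145	1	3
candidate_146	1	1
candidate_147	1	3
candidate_148	1	3
candidate_149	1	4
candidate_150	1	4
candidate_151	1	5
candidate_152	1	1
candidate_153	1	5
candidate_154	1	2
candidate_155	1	3
candidate_156	1	5
candidate_157	1	5
candidate_158	1	5
candidate_159	1	5
candidate_160	1	2
candidate_161	1	2
candidate_162	1	5
candidate_163	1	4
candidate_164	1	5
candidate_165	1	5
candidate_166	1	5
candidate_167	1	5
candidate_168	1	5
candidate_169	1	5
candidate_170	1	1
candidate_171	1	5
candidate_172	1	5
candidate_173	1	3
candidate_174	1	1
candidate_175	1	1
candidate_176	1	1
candidate_177	1	3
candidate_178	1	2
candidate_179	1	5
candidate_180	1	5
candidate_181	1	3
candidate_182	1	5
candidate_183	1	4
candidate_184	1	1
candidate_185	1	1
candidate_186	1	4
candidate_187	1	1
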