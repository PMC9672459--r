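# SYNTHETIC 38-index dinucleotide property set.
# The first six columns are the bundled helical step parameters
# (dinucleotide_indices_core6.tsv); the 32 synth* columns are deterministic
# synthetic pseudo-indices (standard-normal draws, fixed seed 38). This file
# is a synthetic stand-in for a curated 38-index physicochemical collection;
# it is NOT literature data. Encoders standardize every index to mean 0 /
# population SD 1 before use.
# version: 1
dinucleotide	twist	tilt	roll	shift	slide	rise	synth01	synth02	synth03	synth04	synth05	synth06	synth07	synth08	synth09	synth10	synth11	synth12	synth13	synth14	synth15	synth16	synth17	synth18	synth19	synth20	synth21	synth22	synth23	synth24	synth25	synth26	synth27	synth28	synth29	synth30	synth31	synth32
AA	0.026	0.038	0.02	1.69	2.26	7.65	-0.254	-1.056	0.686	0.025	-1.672	-1.484	0.43	0.008	0.886	-0.41	0.061	-1.166	-0.013	1.196	-0.021	0.042	0.699	-0.071	0.98	0.479	-0.071	-1.29	-0.009	-1.202	0.895	-0.286	-0.014	-0.692	1.128	0.217	0.876	0.639
AC	0.036	0.038	0.023	1.32	3.03	8.93	-0.138	-0.501	0.067	2.346	-2.015	1.783	1.026	-0.973	1.255	0.45	-1.785	0.841	0.379	0.373	-0.975	-1.768	-0.863	-1.289	-1.063	0.813	-0.397	-0.096	1.374	0.352	-0.279	1.804	0.355	-0.042	2.001	0.286	-0.032	-0.174
AG	0.031	0.037	0.019	1.46	2.03	7.08	-0.345	-0.896	-1.157	1.257	-0.123	1.191	-0.078	-0.858	0.971	-0.233	-0.21	0.032	-0.039	0.033	-0.069	0.298	-1.381	-0.297	-0.847	0.05	-2.064	1.6	0.561	1.853	0.072	-0.668	-0.026	1.01	-0.364	-1.07	-0.109	0.476
AT	0.033	0.036	0.022	1.03	3.83	9.07	-1.612	1.417	0.493	0.017	0.991	-0.361	0.799	-1.117	-1.3	-0.922	0.517	0.672	-0.486	-0.11	-0.081	-0.141	0.723	-0.936	-0.207	1.118	1.38	1.104	0.762	0.1	1.545	-1.576	-0.365	0.12	0.949	-0.359	2.179	-0.176
CA	0.016	0.025	0.017	1.07	1.78	6.38	-1.289	0.222	-0.254	-2.54	-0.782	0.035	-0.942	-0.727	-0.036	-1.693	0.576	1.611	0.132	0.942	1.502	-0.045	0.533	-1.025	0.962	-1.518	-0.373	-0.16	0.184	-0.526	0.048	-1.074	-0.634	0.007	0.969	-2.029	-2.296	-0.299
CC	0.026	0.042	0.019	1.43	1.65	8.04	-1.711	-1.054	0.946	0.733	-1.759	-0.152	-1.068	0.172	0.97	1.046	-1.187	-0.508	-0.156	-1.358	-0.426	1.268	-1.501	-0.094	-0.227	-1.973	-0.112	-0.429	-0.998	-0.535	-0.065	-0.397	1.002	-0.008	0.772	0.034	-0.591	1.994
CG	0.014	0.026	0.016	1.08	2	6.23	-0.619	-0.09	0.916	0.331	-0.036	0.018	0.471	2.533	0.013	0.557	-0.127	-2.181	-0.056	0.859	-0.847	-1.217	-0.668	0.925	0.649	-1.178	-0.344	-0.783	0.145	-0.705	0.342	0.474	1.162	-0.519	1.28	1.362	0.43	1.761
CT	0.031	0.037	0.019	1.46	2.03	7.08	2.728	-1.761	2.705	1.75	-0.747	-0.718	0.24	-0.091	0.836	0.951	-0.103	0.751	-0.43	0.339	-0.581	1.043	-2.399	-1.432	0.46	-0.878	-1.306	0.531	1.32	0.412	1.312	1.458	0.203	-0.512	-0.864	-0.731	0.171	-0.656
GA	0.025	0.038	0.02	1.32	1.93	8.56	-1.356	-1.112	0.075	-0.38	0.846	-0.63	-0.312	0.613	-0.931	0.435	1.354	0.87	0.97	-0.391	0.785	-0.169	-0.34	1.411	-0.852	-0.521	0.104	0.272	2.306	1.896	0.964	-1.639	0.208	0.553	-0.234	0.472	-0.87	-0.221
GC	0.025	0.036	0.026	1.2	2.61	9.53	-1.431	-1.161	1.103	1.049	0.784	-0.595	1.291	-0.93	-0.806	0.411	0.625	0.77	-0.172	-0.41	-0.081	-0.696	-0.979	-1.582	-0.328	-0.526	0.166	-0.547	1.048	-0.146	2.593	2.129	-1.165	1.232	0.928	-0.399	-0.308	-0.325
GG	0.026	0.042	0.019	1.43	1.65	8.04	-0.423	-0.513	0.218	-0.752	0.479	-0.042	1.544	-0.633	-0.605	-0.096	0.438	-0.4	-0.508	-0.823	-0.983	-1.486	0.673	-0.607	2.787	-0.105	0.149	-1.232	-0.137	0.545	0.146	0.785	-0.105	1.759	1.308	-1.149	-1.03	-1.644
GT	0.036	0.038	0.023	1.32	3.03	8.93	-2.009	-1.561	1.387	-0.35	0.626	-0.077	-0.902	1.426	-0.305	-0.926	2.23	-0.556	0.406	1.028	0.363	-0.506	-0.404	0.172	1.263	0.605	1.639	0.278	1.177	-0.744	-1.59	-0.989	-0.717	-0.436	-0.989	-0.422	-1.871	-0.356
TA	0.017	0.018	0.016	0.72	1.2	6.23	-0.115	0.323	-0.28	1.404	0.782	0.569	0.981	-0.851	1.049	-0.002	-0.506	1.362	-0.563	-0.721	1.219	-0.372	0.235	-0.127	-0.1	-0.323	0.058	0.228	0.853	-0.697	-0.206	-1.44	-0.628	0.252	0.302	-0.347	-0.011	-0.319
TC	0.025	0.038	0.02	1.32	1.93	8.56	-0.423	0.587	-0.291	-0.932	0.936	-0.508	0.467	-0.246	0.044	0.876	-0.103	0.285	-2.24	-0.123	-0.284	0.329	0.353	-0.563	1.728	-0.607	-0.295	-0.012	-0.664	-1.74	1.371	-0.775	-0.283	-0.237	-0.141	-1.668	-0.129	-1.442
TG	0.016	0.025	0.017	1.07	1.78	6.38	0.988	0.575	-1.143	1.076	-0.105	-1.422	-0.194	-0.603	-0.084	-0.904	0.385	-0.341	-1.125	-0.362	0.443	-0.459	0.189	-2.088	-0.522	-0.212	-0.458	0.513	0.435	-0.7	-0.756	0.049	-0.57	-0.043	0.181	0.172	1.424	0.411
TT	0.026	0.038	0.02	1.69	2.26	7.65	-1.045	0.832	0.59	1.158	-0.481	0.82	-1.107	1.666	-1.608	-1.057	0.239	1.307	-1.455	-0.748	0.823	0.644	-0.517	0.276	-0.154	0.141	1.753	0.26	0.371	0.343	1.298	1.236	0.086	-2.001	0.875	-1.145	-0.131	-1.026
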