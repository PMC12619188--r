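map00001	Glycerophospholipid metabolism (synthetic)	C00001	C00002	C00003	C00004	C00005	C00006	C00007	C00008	C00009	C00010
map00002	Synthetic pathway 2	C00103	C00015	C00118	C00136	C00067	C00022	C00147	C00059	C00090	C00012	C00040	C00031	C00134	C00021
map00003	Synthetic pathway 3	C00139	C00102	C00026	C00130	C00100	C00124	C00123	C00036
map00004	Synthetic pathway 4	C00003	C00109	C00088	C00041	C00022	C00008	C00147	C00031	C00034	C00032	C00140	C00072	C00148	C00074	C00122	C00059	C00114	C00087	C00141	C00117	C00062	C00055	C00139	C00028	C00016	C00050	C00018	C00040	C00093
map00005	Synthetic pathway 5	C00010	C00109	C00064	C00121	C00147	C00056	C00022	C00006	C00043	C00077
map00006	Synthetic pathway 6	C00124	C00018	C00017	C00033	C00044	C00032	C00048	C00058	C00113	C00008	C00009	C00086	C00116	C00078	C00043	C00088
map00007	Synthetic pathway 7	C00061	C00028	C00054	C00104	C00018	C00146	C00109	C00087	C00116	C00082	C00008	C00081	C00112	C00079	C00043	C00075	C00090	C00076	C00094	C00125	C00129	C00100	C00010	C00103
map00008	Synthetic pathway 8	C00141	C00039	C00122	C00068	C00138	C00148	C00142	C00043	C00143	C00010	C00082	C00096	C00023	C00060	C00066	C00011
map00009	Synthetic pathway 9	C00002	C00149	C00001	C00014	C00079	C00111	C00150	C00119	C00146	C00075	C00054
map00010	Synthetic pathway 10	C00025	C00034	C00088	C00099	C00095	C00057	C00094	C00104
map00011	Synthetic pathway 11	C00053	C00018	C00144	C00139	C00039	C00045	C00121	C00072	C00003	C00056	C00057	C00014	C00108	C00046	C00142	C00107	C00079
map00012	Synthetic pathway 12	C00149	C00087	C00030	C00083	C00109	C00059	C00031	C00144	C00102	C00091	C00123	C00103	C00016	C00070	C00002	C00061	C00093	C00134	C00023	C00106	C00085
map00013	Synthetic pathway 13	C00005	C00100	C00030	C00142	C00040	C00052	C00027	C00120	C00064	C00119	C00141	C00026	C00034	C00131	C00067	C00092	C00136	C00132	C00086	C00008	C00096	C00079
map00014	Synthetic pathway 14	C00104	C00046	C00063	C00145	C00131	C00006	C00142	C00014	C00024	C00062	C00086	C00124	C00056	C00074	C00137	C00129	C00035	C00126	C00073	C00079	C00117	C00001
map00015	Synthetic pathway 15	C00059	C00091	C00107	C00138	C00143	C00033	C00114	C00119	C00095	C00010	C00112	C00007	C00142	C00141	C00122	C00065	C00009	C00061	C00027	C00030	C00039	C00036	C00113	C00022	C00006	C00100	C00069	C00060	C00021
map00016	Synthetic pathway 16	C00114	C00062	C00016	C00111	C00105	C00130	C00126	C00125
map00017	Synthetic pathway 17	C00001	C00080	C00130	C00010	C00092	C00084	C00137	C00090	C00113	C00142	C00012	C00146	C00026	C00019	C00099	C00053	C00059	C00097	C00021	C00043	C00140	C00069	C00098	C00055	C00106	C00139	C00015	C00003	C00076	C00029
map00018	Synthetic pathway 18	C00132	C00034	C00061	C00119	C00065	C00118	C00025	C00077	C00085	C00143	C00031	C00078	C00013	C00100	C00044	C00115	C00007	C00148	C00093	C00121
map00019	Synthetic pathway 19	C00091	C00132	C00009	C00135	C00031	C00023	C00019	C00057	C00098	C00125	C00092	C00035	C00094	C00141	C00118	C00068	C00008	C00044	C00037	C00117	C00007	C00102	C00079	C00022
map00020	Synthetic pathway 20	C00083	C00016	C00071	C00137	C00050	C00124	C00014	C00150	C00105	C00148	C00122	C00098	C00084	C00116	C00068	C00030	C00074	C00036	C00080	C00044
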