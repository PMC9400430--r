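pair_id	coef	hr	hr_ci_low	hr_ci_high	p
USP30-AS1|AC008649.2	-0.37265831	0.688900583	0.503499614	0.942570759	0.019821465
AC007389.5|AC073046.1	-0.393910582	0.674414359	0.503652282	0.903072901	0.00818398
AC005884.2|AL163051.1	0.506623749	1.659678235	1.124429293	2.44971548	0.010762253
U62317.1|HOXB-AS2	-0.522539129	0.593012898	0.434220372	0.80987517	0.001015862
BMPR1B-DT|UNC5B-AS1	-0.731071092	0.481393097	0.334014628	0.693799896	0.00000884
AL035701.1|AC106900.1	-0.540417777	0.582504844	0.429107585	0.790738512	0.000528994
NR4A1AS|LINC00893	0.396416384	1.486488139	1.108818372	1.992794349	0.008033751
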