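# Promoter islands of E. coli K-12 MG1655 (U00096.2): 78 regions with >= 8
# predicted TSPs in every sliding 100-bp window over >= 300 bp.
# five_prime_end: leftmost base of the island (1-based, forward strand).
# length: island length in bp; interval = [five_prime_end, five_prime_end + length - 1].
# A: overlaps a genomic island called by IslandViewer ("+").
# B: overlaps a genomic island called by GIST ("+").
# C, D, E: number of associated foreign genes predicted by Nakamura et al.,
#          Lawrence & Ochman, and Price et al., respectively.
# H: H-NS interaction evidence. G = Grainger et al.; K = Kahramanoglou et al.
#    and Oshima et al.; O = Oshima et al. and Grainger et al.; A = all studies.
five_prime_end	length	genes	A	B	C	D	E	H
29150	313	dapB(+)/carA(+)						G
83898	426	leuL(-)/leuO(+)		+	1			A
121694	343	aroP(-)/pdhR(+)					1	G
156927	379	yadN(-)/folK(-)		+	1	1		A
310529	398	ecpR(-)/ykgL(+)	+		2		1	A
383994	309	yaiS(-)/tauA(+)			1	1	1	A
522099	304	ybbP(+)/rhsD(+)		+	1	1	1	A
557105	351	folD(-)/sfmA(+)	+		1	1	1	K
576129	354	nmpC(-)/essD(+)	+	+		2		A
582438	1016	tfaX(+)/appY(+)	+	+	1	1		A
583602	323	appY(+)/ompT(-)	+	+	2	2		A
584821	351	ompT(-)/envY(-)	+	+	1	1		A
751980	413	ybgD(-)/gltA(-)		+	1	1		A
953696	434	focA(-)/ycaO(-)		+				K
996773	328	ssuE(-)/elfA(+)			1	1		A
1196665	422	ymfD(-)/ymfE(-)	+	+	1	1	1	A
1210318	317	mcrA(+)/icdC(+)	+	+	1	1	1	A
1255333	301	ycgV(-)/ychF(-)			1			A
1332795	340	cysB(+)/ymiA(+)						K
1432784	339	ynaE(-)/uspF(-)		+	1	1		O
1463061	385	paaY(+)/ydbA(+)		+			1	K
1527917	612	ydcD(+)/yncI(+)		+	1	1		A
1570060	392	gadB(-)/pqqL(-)						A
1581576	327	ydeO(-)/safA(-)	+	+	1	1		A
1596197	345	ydeK(-)/lsrK(-)			1			A
1636643	433	cspI(-)/ydfP(-)	+	+		1		A
1752593	318	ydhY(-)/ydhZ(-)		+	1			A
1811053	320	ydjO(-)/cedA(-)			1	1		K
1868534	304	yeaI(+)		+	1	1		A
1903241	302	yobD(+)/mntP(+)			1		1	K
2054637	373	amn(+)/yeeN(+)	+	+	1	1	1	K
2101895	370	wbbK(-)	+	+	2	2	1	K
2190229	357	yehD(-)/yehE(-)	+	+	1	1		K
2342143	534	yfaL(-)/ypaB(-)		+	1		1	A
2363626	315	ais(-)/arnB(+)		+	1	1	1	K
2453647	489	yfcV(-)/sixA(-)		+				K
2461920	303	yfdF(+)/mlaA(-)			1	1		A
2467210	667	yfdI(+)	+	+	1	1	1	A
2468092	410	yfdI(+)/tfaS(+)	+	+	1	2	1	A
2882192	323	casA(-)/cas3(-)	+	+	1	1		K
2901670	347	ygcE(+)/queE(-)		+			1	A
2903475	338	queE(-)/ygcG(+)		+	1	1	1	K
2986202	358	yqeH(+)/yqeI(+)		+	1	1		A
2988974	339	ygeF(+)/ygeG(+)		+	1	1	1	A
2989603	468	ygeG(+)/ygeH(+)		+	1	1	1	A
2991357	340	ygeH(+)/ygeI(+)		+	1	1		A
2992989	612	ygeK(-)/ygeM(-)		+	2	2		A
3117080	374	yghJ(-)/glcA(-)					1	A
3265097	477	tdcA(-)/tdcR(+)		+	2	2		K
3266734	706	yhaC(+)		+	1	1		A
3285165	325	agaI(+)/yraH(+)		+	1	1	1	K
3383263	333	argR(+)/yhcN(+)				1		O
3453428	392	gspA(-)/gspC(+)			2	1		K
3580023	317	yhhZ(+)		+	1	1		K
3581031	347	yrhA(+)		+	1	1		K
3631905	345	yhiL(-)		+	1	1		A
3632424	449	yhiL(-)/yhiM(+)		+	2	2	1	K
3648929	470	arsC(+)/yhiS(+)		+	1	1		A
3651288	639	insH_11(-)/slp(+)		+	1	2	1	K
3767592	418	yibV(+)/yibH(-)		+				A
3794947	496	waaC(+)/rfaL(+)	+	+	1	1		A
3797063	551	waaK(-)/rfaZ(-)	+	+	1	1	1	A
3798731	723	waaY(-)/waaJ(-)	+	+	1	1	1	A
3802145	1102	waaB(-)/waaP(-)	+	+	2	2	2	A
3834632	331	selC(+)/setC(+)			1			A
3920739	440	atpI(-)/rsmG(-)			1			K
4000528	663	yigF(-)/yigG(-)			1	1		A
4219964	389	arpA(-)		+	1	1		A
4248719	304	malM(+)/yjbI(+)		+	1	1	1	A
4249440	561	yjbI(+)		+	1	1	1	K
4258129	526	zur(-)/yjbL(+)		+	1	1		A
4266514	318	tyrB(+)/yjbS(-)		+			1	K
4280619	615	yjcF(-)/actP(-)		+	1	1	1	A
4474585	660	yjgL(+)	+	+	1	1		A
4537484	311	nanC(-)/fimB(+)	+	+	2	2	1	K
4539580	404	fimB(+)/fimE(+)	+	+	1	1		K
4540575	443	fimE(+)/fimA(+)	+	+		1	1	A
4554354	526	yjiC(-)/iraD(+)		+	2	1		K
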